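#' @title Peptide b/y fragment-ion computation
#' @name nucdyn-ions
#' @description
#' Monoisotopic b/y fragment-ion m/z calculation and spectrum annotation
#' for modified peptides, the computation behind MS/MS evidence for
#' histone PTMs such as CENP-A K124 acetylation/methylation on the
#' tryptic peptide VTLFPKDVQLAR. Constants: proton 1.007276 Da, water
#' 18.010565 Da, residue masses to five decimals.
NULL

.proton <- 1.007276
.water <- 18.010565

.residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

.builtin_mods <- c(
  acetyl = 42.010565, methyl = 14.015650, dimethyl = 28.031300,
  trimethyl = 42.046950, phospho = 79.966331, gg = 114.042927
)

#' Modification registry
#'
#' Named monoisotopic mass deltas (Da). Built-ins: acetyl, methyl,
#' dimethyl, trimethyl, phospho, gg (ubiquitin remnant).
#'
#' @param extra named numeric vector of additional modifications.
#' @return named numeric vector of mass deltas.
#' @export
modification_registry <- function(extra = NULL) {
  reg <- .builtin_mods
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop("extra modifications must be named")
    }
    if (any(names(extra) %in% names(reg))) {
      stop("modification name collides with a built-in")
    }
    reg <- c(reg, extra)
  }
  if (any(!is.finite(reg))) stop("modification deltas must be finite")
  reg
}

#' Construct a (modified) peptide
#'
#' @param sequence uppercase one-letter amino-acid string (canonical 20).
#' @param mods named list/vector: names are modification names from the
#'   registry, values are 1-based sequence positions. May also be given
#'   as `c("6" = "acetyl")` style position->name; both orientations are
#'   accepted as long as one side parses as positions.
#' @param nterm_delta,cterm_delta terminal mass deltas in Da (default 0).
#' @param registry modification registry (default built-ins).
#' @return object of class `ncp_peptide` with per-residue masses resolved.
#' @export
peptide <- function(sequence, mods = NULL, nterm_delta = 0, cterm_delta = 0,
                    registry = modification_registry()) {
  res <- strsplit(sequence, "")[[1]]
  if (length(res) == 0L) stop("empty peptide sequence")
  bad <- setdiff(res, names(.residue_masses))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  mod_at <- stats::setNames(character(length(res)), NULL)
  mod_at[] <- ""
  if (!is.null(mods) && length(mods)) {
    nm <- names(mods); vl <- as.character(unlist(mods))
    pos_from_names <- suppressWarnings(as.integer(nm))
    if (!is.null(nm) && !anyNA(pos_from_names)) {
      positions <- pos_from_names; modnames <- vl
    } else {
      positions <- suppressWarnings(as.integer(vl)); modnames <- nm
      if (anyNA(positions)) stop("modification positions must be integers")
    }
    for (k in seq_along(positions)) {
      p <- positions[k]
      if (p < 1L || p > length(res)) {
        stop("modification position out of range: ", p)
      }
      if (!modnames[k] %in% names(registry)) {
        stop("unknown modification: ", modnames[k])
      }
      mod_at[p] <- modnames[k]
    }
  }
  masses <- unname(.residue_masses[res]) +
    ifelse(mod_at == "", 0, registry[mod_at])
  masses <- unname(masses)
  structure(list(sequence = sequence, residues = res, mods = mod_at,
                 residue_masses = masses,
                 nterm_delta = nterm_delta, cterm_delta = cterm_delta),
            class = "ncp_peptide")
}

#' @export
print.ncp_peptide <- function(x, ...) {
  lab <- x$residues
  has <- nzchar(x$mods)
  lab[has] <- sprintf("%s(%s)", lab[has], x$mods[has])
  cat(sprintf("<ncp_peptide> %s, M = %.5f Da\n", paste(lab, collapse = ""),
              peptide_mass(x)))
  invisible(x)
}

#' Monoisotopic neutral peptide mass
#'
#' Sum of (modified) residue masses plus water plus any terminal deltas.
#'
#' @param p an `ncp_peptide`.
#' @return neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(p) {
  sum(p$residue_masses) + .water + p$nterm_delta + p$cterm_delta
}

#' Theoretical b/y fragment-ion series
#'
#' Singly charged: `b_i = sum(first i residues) + proton`,
#' `y_i = sum(last i residues) + water + proton` (terminal deltas included
#' on their respective ends). For charge z the m/z is
#' `(neutral_fragment + z * proton) / z`.
#'
#' @param p an `ncp_peptide`.
#' @param charges integer charges, subset of 1:3 (default 1:2).
#' @return data frame of class `ncp_ion_table` rows: `series` ("b"/"y"),
#'   `index` (1..n-1), `charge`, `theoretical_mz`.
#' @export
ion_series <- function(p, charges = 1:2) {
  if (!all(charges %in% 1:3)) stop("charges must be a subset of 1:3")
  n <- length(p$residues)
  if (n < 2L) stop("fragment ions need at least 2 residues")
  b_neutral <- cumsum(p$residue_masses)[seq_len(n - 1L)] + p$nterm_delta
  y_neutral <- rev(cumsum(rev(p$residue_masses)))[2:n] + .water +
    p$cterm_delta
  # y_neutral is ordered y_{n-1} .. y_1; re-order ascending by index
  y_neutral <- rev(y_neutral)
  out <- do.call(rbind, lapply(sort(charges), function(z) {
    rbind(
      data.frame(series = "b", index = seq_len(n - 1L), charge = z,
                 theoretical_mz = (b_neutral + z * .proton) / z,
                 stringsAsFactors = FALSE),
      data.frame(series = "y", index = seq_len(n - 1L), charge = z,
                 theoretical_mz = (y_neutral + z * .proton) / z,
                 stringsAsFactors = FALSE)
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("ncp_ion_table", class(out))
  out
}

#' Precursor (parent) ion m/z
#'
#' @param p an `ncp_peptide`.
#' @param z charge (>= 1).
#' @return `(neutral mass + z * proton) / z`.
#' @export
precursor_mz <- function(p, z) {
  if (z < 1) stop("charge must be >= 1")
  (peptide_mass(p) + z * .proton) / z
}

#' Annotate an observed peak list against the theoretical ion series
#'
#' Each theoretical ion is matched to the nearest observed peak within
#' `tol` Da; a peak may satisfy several theoreticals (such matches are
#' flagged ambiguous); unmatched ions are retained with `NA` observed
#' m/z. The default 0.4 Da tolerance suits ion-trap CID spectra.
#'
#' @param p an `ncp_peptide`.
#' @param peaks numeric vector of observed m/z values.
#' @param tol match tolerance in Da (> 0, default 0.4).
#' @param charges charges for the theoretical series.
#' @return the [ion_series()] data frame with added `matched_mz`,
#'   `delta_da` and `ambiguous` columns.
#' @export
annotate_spectrum <- function(p, peaks, tol = 0.4, charges = 1:2) {
  if (tol <= 0) stop("tol must be > 0")
  ions <- ion_series(p, charges)
  ions$matched_mz <- NA_real_
  ions$delta_da <- NA_real_
  ions$ambiguous <- FALSE
  if (length(peaks)) {
    peak_of <- integer(nrow(ions))
    for (r in seq_len(nrow(ions))) {
      d <- abs(peaks - ions$theoretical_mz[r])
      j <- which.min(d)
      if (d[j] <= tol) {
        ions$matched_mz[r] <- peaks[j]
        ions$delta_da[r] <- peaks[j] - ions$theoretical_mz[r]
        peak_of[r] <- j
      }
    }
    shared <- table(peak_of[peak_of > 0])
    amb <- as.integer(names(shared)[shared > 1])
    ions$ambiguous <- peak_of %in% amb & peak_of > 0
  }
  ions
}

#' Render the residue-by-residue fragment table
#'
#' One row per residue with ascending b index paired with the descending
#' y index (`y_{n-i+1}` opposite residue i), the layout used in published
#' fragment tables; modified residues are labelled "K-Acetyl" style.
#'
#' @param p an `ncp_peptide`.
#' @param charges charges to tabulate (default 1:2).
#' @return data frame with `b_index`, one `b{z}` column per charge, `seq`,
#'   per-charge `y{z}` columns, `y_index`. b_n and y_n positions that do
#'   not exist (full-length fragments) are `NA`.
#' @export
render_ion_table <- function(p, charges = 1:2) {
  ions <- ion_series(p, charges)
  n <- length(p$residues)
  lab <- p$residues
  has <- nzchar(p$mods)
  cap <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
  lab[has] <- sprintf("%s-%s", lab[has], cap(p$mods[has]))
  out <- data.frame(b_index = seq_len(n), stringsAsFactors = FALSE)
  for (z in sort(charges)) {
    bz <- ions[ions$series == "b" & ions$charge == z, ]
    out[[sprintf("b%d", z)]] <- c(bz$theoretical_mz[match(seq_len(n - 1L),
                                                          bz$index)], NA)[seq_len(n)]
  }
  out$seq <- lab
  for (z in sort(charges)) {
    yz <- ions[ions$series == "y" & ions$charge == z, ]
    yi <- n - seq_len(n) + 1L          # residue i pairs with y_{n-i+1}
    out[[sprintf("y%d", z)]] <- yz$theoretical_mz[match(yi, yz$index)]
  }
  out$y_index <- n - seq_len(n) + 1L
  out$y_index[1] <- NA                 # y_n is the whole peptide, not listed
  out
}
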
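#' Per-frame scalar time series
#'
#' @param name observable name.
#' @param units units string (e.g. "A", "deg").
#' @param times per-frame times in ns.
#' @param values per-frame scalar values (finite, same length as times).
#' @return object of class `ncp_series`.
#' @export
time_series <- function(name, units, times, values) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(!is.finite(values))) stop("series values must be finite")
  structure(list(name = name, units = units, times = as.numeric(times),
                 values = as.numeric(values)), class = "ncp_series")
}

#' @export
print.ncp_series <- function(x, ...) {
  cat(sprintf("<ncp_series> %s [%s], %d frames, mean %.4g, sd %.4g\n",
              x$name, x$units, length(x$values), mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Distribution summary of a time series
#'
#' @param ts an `ncp_series`.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list with `mean`, `variance`, `n`, and `histogram`
#'   (data frame of bin_lo, bin_hi, count).
#' @export
series_summary <- function(ts, breaks = "Sturges") {
  h <- graphics::hist(ts$values, breaks = breaks, plot = FALSE)
  nb <- length(h$counts)
  list(mean = mean(ts$values),
       variance = stats::var(ts$values),
       n = length(ts$values),
       histogram = data.frame(bin_lo = h$breaks[seq_len(nb)],
                              bin_hi = h$breaks[seq_len(nb) + 1L],
                              count = h$counts))
}

#' Write a time series (frame, time_ns, value) as TSV
#' @param ts an `ncp_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(ts, path) {
  write_tsv(data.frame(frame = seq_along(ts$values), time_ns = ts$times,
                       value = ts$values), path)
}

# Kabsch: optimal proper rotation R (applied as X %*% R) mapping centered
# X onto centered Y
.kabsch <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body superposition onto the time-average reference
#'
#' Each frame is least-squares fitted (optimal proper rotation +
#' translation, mass-unweighted) on the `ref_sel` atoms onto their
#' time-average structure, following standard essential-dynamics practice.
#' The time average is obtained by first aligning all frames to frame 1
#' and then re-fitting onto the resulting mean, which converges for
#' equilibrium-like trajectories.
#'
#' @param traj an `ncp_trajectory`.
#' @param ref_sel selection of fitting atoms (>= 3, non-collinear); default
#'   all atoms.
#' @param model_topo optional `ncp_topology` needed if `ref_sel` names roles.
#' @return the superposed `ncp_trajectory`.
#' @export
superpose <- function(traj, ref_sel = NULL, model_topo = NULL) {
  idx <- if (is.null(ref_sel)) seq_len(n_atoms(traj))
         else resolve_selection(ref_sel, traj$structure, model_topo)
  if (length(idx) < 3L) stop("reference selection needs >= 3 atoms")
  ref0 <- frame_coords(traj, 1L, idx)
  sv <- svd(scale(ref0, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("reference selection is collinear/degenerate; cannot superpose")
  }
  fit_all <- function(traj, target) {
    nf <- traj$n_frames
    xyz <- traj$xyz
    tc <- colMeans(target)
    t0 <- sweep(target, 2, tc)
    out <- matrix(NA_real_, nf, ncol(xyz))
    all_idx <- seq_len(ncol(xyz) / 3L)
    for (f in seq_len(nf)) {
      X <- frame_coords(traj, f, idx)
      xc <- colMeans(X)
      R <- .kabsch(sweep(X, 2, xc), t0)
      full <- frame_coords(traj, f, all_idx)
      moved <- sweep(sweep(full, 2, xc) %*% R, 2, tc, `+`)
      out[f, ] <- as.vector(t(moved))
    }
    trajectory(traj$structure, out, traj$times, traj$metadata)
  }
  pass1 <- fit_all(traj, ref0)
  mean_ref <- matrix(colMeans(pass1$xyz[, xyz_cols(idx), drop = FALSE]),
                     ncol = 3L, byrow = TRUE)
  fit_all(traj, mean_ref)
}

#' Root-mean-square fluctuation with blocked error estimate
#'
#' RMSF of atom i is `sqrt(mean_t ||x_i(t) - <x_i>||^2)` about the
#' time-average position, computed on a superposed trajectory. The blocked
#' estimate splits the window into `block_count` contiguous blocks
#' (default thirds), computes RMSF per block about each block's own mean,
#' and reports the standard deviation of the block values as the error
#' bar.
#'
#' @param traj a superposed `ncp_trajectory`.
#' @param sel atom selection (default all atoms).
#' @param cfg an `ncp_config` (`block_count` is used).
#' @param topo optional `ncp_topology` if `sel` names roles.
#' @return data frame with columns `atom`, `chain_id`, `residue_index`,
#'   `name`, `rmsf`, `block_sd`, plus attribute `block_rmsf` (atoms x
#'   blocks matrix).
#' @export
rmsf <- function(traj, sel = NULL, cfg = analysis_config(), topo = NULL) {
  idx <- if (is.null(sel)) seq_len(n_atoms(traj))
         else resolve_selection(sel, traj$structure, topo)
  nf <- traj$n_frames
  if (nf < cfg$block_count) stop("fewer frames than blocks")
  X <- traj$xyz[, xyz_cols(idx), drop = FALSE]
  rmsf_of <- function(M) {
    dev <- sweep(M, 2, colMeans(M))
    msd_per_col <- colMeans(dev^2)
    sqrt(colSums(matrix(msd_per_col, nrow = 3L)))
  }
  whole <- rmsf_of(X)
  blocks <- split(seq_len(nf),
                  cut(seq_len(nf), cfg$block_count, labels = FALSE))
  block_rmsf <- vapply(blocks, function(rows) rmsf_of(X[rows, , drop = FALSE]),
                       numeric(length(idx)))
  at <- traj$structure$atoms[idx, , drop = FALSE]
  out <- data.frame(atom = idx, chain_id = at$chain_id,
                    residue_index = at$residue_index, name = at$name,
                    rmsf = whole,
                    block_sd = apply(block_rmsf, 1, stats::sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "block_rmsf") <- block_rmsf
  out
}

#' Per-base-pair DNA RMSF
#'
#' Averages the per-strand representative-atom RMSF values of each base
#' pair (the DNA convention of reporting the nucleic-acid average).
#'
#' @param rmsf_df output of [rmsf()] covering both DNA strands' P atoms.
#' @param topo an `ncp_topology`.
#' @return data frame with `bp` (strand-I residue index), `rmsf`,
#'   `block_sd` (averaged over the two strands).
#' @export
rmsf_by_basepair <- function(rmsf_df, topo) {
  chain_I <- role_chain(topo, "DNA_I")
  chain_J <- role_chain(topo, "DNA_J")
  bp <- topo$basepair_map
  iv <- rmsf_df[rmsf_df$chain_id == chain_I & rmsf_df$name == "P", ]
  jv <- rmsf_df[rmsf_df$chain_id == chain_J & rmsf_df$name == "P", ]
  i_r <- iv$rmsf[match(bp[, 1], iv$residue_index)]
  j_r <- jv$rmsf[match(bp[, 2], jv$residue_index)]
  i_s <- iv$block_sd[match(bp[, 1], iv$residue_index)]
  j_s <- jv$block_sd[match(bp[, 2], jv$residue_index)]
  keep <- !is.na(i_r) & !is.na(j_r)
  data.frame(bp = bp[keep, 1], rmsf = (i_r + j_r)[keep] / 2,
             block_sd = (i_s + j_s)[keep] / 2)
}

# mass-weighted COM per frame for an atom index set: n_frames x 3
.com_series <- function(traj, idx) {
  m <- traj$structure$atoms$mass[idx]
  if (sum(m) <= 0) stop("zero total mass in COM group")
  w <- m / sum(m)
  vapply(1:3, function(ax) {
    as.vector(traj$xyz[, 3L * (idx - 1L) + ax, drop = FALSE] %*% w)
  }, numeric(traj$n_frames))
}

#' Mass-weighted center-of-mass distance between two groups
#'
#' Per-frame distance between the mass-weighted centers of mass of two
#' atom groups (e.g. the CENP-A/H4 and CENP-A'/H4' dimers), with a
#' distribution summary whose mean and variance are the standard
#' comparands between simulation regimes.
#'
#' @param traj an `ncp_trajectory`.
#' @param topo an `ncp_topology`.
#' @param groupA,groupB selections (non-empty, positive masses).
#' @return list with `series` (`ncp_series`) and `summary`
#'   (from [series_summary()]).
#' @export
com_distance_series <- function(traj, topo, groupA, groupB) {
  ia <- resolve_selection(groupA, traj$structure, topo)
  ib <- resolve_selection(groupB, traj$structure, topo)
  d <- sqrt(rowSums((.com_series(traj, ia) - .com_series(traj, ib))^2))
  ts <- time_series("com_distance", "A", traj$times, d)
  list(series = ts, summary = series_summary(ts))
}

# P atoms of a base-pair row: c(strand I atom, strand J atom)
.bp_atoms <- function(model, topo, bp_row) {
  chain_I <- role_chain(topo, "DNA_I")
  chain_J <- role_chain(topo, "DNA_J")
  i <- topo$basepair_map[bp_row, 1]; j <- topo$basepair_map[bp_row, 2]
  ai <- .atoms_of(model, chain_I, i, "P")
  aj <- .atoms_of(model, chain_J, j, "P")
  if (length(ai) != 1L || length(aj) != 1L) {
    stop(sprintf("missing representative P atom at base pair (%d, %d)", i, j))
  }
  c(ai, aj)
}

#' DNA end-to-pseudo-dyad distance series
#'
#' Per-frame distance between the center of mass of the terminal base
#' pair's representative P atoms (entry or exit end) and the center of
#' mass of the pseudo-dyad base pair's P atoms. The entry end is the
#' strand-I 5' terminus side by default, as recorded in the topology.
#'
#' @param traj an `ncp_trajectory`.
#' @param topo an `ncp_topology` with `dyad_pair` and `basepair_map`.
#' @param end `"entry"` or `"exit"`.
#' @param cfg unused placeholder for interface uniformity.
#' @return list with `series` and `summary` as in [com_distance_series()].
#' @export
dna_end_to_dyad_series <- function(traj, topo, end = c("entry", "exit"),
                                   cfg = analysis_config()) {
  end <- match.arg(end)
  n_bp <- nrow(topo$basepair_map)
  first_is_entry <- topo$entry_end == "first"
  row <- if ((end == "entry") == first_is_entry) 1L else n_bp
  dyad_row <- which(topo$basepair_map[, 1] == topo$dyad_pair[1])
  e_idx <- .bp_atoms(traj$structure, topo, row)
  d_idx <- .bp_atoms(traj$structure, topo, dyad_row)
  d <- sqrt(rowSums((.com_series(traj, e_idx) - .com_series(traj, d_idx))^2))
  ts <- time_series(paste0("dna_", end, "_to_dyad"), "A", traj$times, d)
  list(series = ts, summary = series_summary(ts))
}

#' DNA groove width series (cross-strand P-P convention)
#'
#' Groove width at strand-I residue i is the per-frame distance between
#' the P bead of strand-I residue i and the P bead of strand-J residue
#' `basepair_map(i) + k` (k = 3 for the minor groove, k = 7 for the major
#' groove, in strand J's own residue numbering), minus a constant
#' phosphate-exclusion diameter of 5.8 Angstrom, floored at 0. This is a
#' documented P-P convention, not a curvilinear helicoidal algorithm.
#'
#' @param traj an `ncp_trajectory`.
#' @param topo an `ncp_topology`.
#' @param groove `"minor"` or `"major"`.
#' @param position strand-I residue index (duplex interior).
#' @return an `ncp_series` in Angstrom.
#' @export
groove_width_series <- function(traj, topo, groove = c("minor", "major"),
                                position) {
  groove <- match.arg(groove)
  k <- if (groove == "minor") 3L else 7L
  bp <- topo$basepair_map
  row <- which(bp[, 1] == position)
  if (length(row) != 1L) stop("position ", position, " not in basepair_map")
  partner <- bp[row, 2] + k
  if (!partner %in% bp[, 2]) {
    stop(sprintf("groove offset +%d from residue %d runs off strand J", k,
                 bp[row, 2]))
  }
  chain_I <- role_chain(topo, "DNA_I")
  chain_J <- role_chain(topo, "DNA_J")
  ai <- .atoms_of(traj$structure, chain_I, position, "P")
  aj <- .atoms_of(traj$structure, chain_J, partner, "P")
  if (length(ai) != 1L || length(aj) != 1L) {
    stop("missing P atom for groove measurement at position ", position)
  }
  ca <- traj$xyz[, xyz_cols(ai), drop = FALSE]
  cb <- traj$xyz[, xyz_cols(aj), drop = FALSE]
  d <- sqrt(rowSums((ca - cb)^2))
  time_series(paste0(groove, "_groove_w", position), "A", traj$times,
              pmax(d - 5.8, 0))
}

# dominant principal axis (unit vector) of a bead set; sign fixed by
# making the largest-magnitude component positive
.principal_axis <- function(X) {
  v <- svd(sweep(X, 2, colMeans(X)))$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Helix scissoring angle series (alpha2 vs alpha3 of CENP-A)
#'
#' Per-frame angle in degrees between the dominant principal axes of the
#' alpha2 and alpha3 Calpha bead sets of the CENP-A chain (ranges taken
#' from the topology's named segments). Axis signs are fixed by
#' continuity with the previous frame so the angle evolves smoothly.
#'
#' @param traj an `ncp_trajectory`.
#' @param topo an `ncp_topology` whose `cterm_ranges[["CENP-A"]]` provides
#'   `alpha2` and `alpha3` ranges (each >= 4 residues).
#' @param role which chain's helices (default "CENP-A").
#' @return an `ncp_series` in degrees.
#' @export
scissoring_series <- function(traj, topo, role = "CENP-A") {
  rng <- topo$cterm_ranges[[role]]
  if (is.null(rng$alpha2) || is.null(rng$alpha3)) {
    stop("topology lacks alpha2/alpha3 ranges for role ", role)
  }
  for (seg in c("alpha2", "alpha3")) {
    if (diff(range(rng[[seg]])) + 1L < 4L) {
      stop(seg, " range has fewer than 4 residues")
    }
  }
  chain <- role_chain(topo, role)
  i2 <- .atoms_of(traj$structure, chain, rng$alpha2[1]:rng$alpha2[2])
  i3 <- .atoms_of(traj$structure, chain, rng$alpha3[1]:rng$alpha3[2])
  nf <- traj$n_frames
  ang <- numeric(nf)
  prev2 <- prev3 <- NULL
  for (f in seq_len(nf)) {
    a2 <- .principal_axis(frame_coords(traj, f, i2))
    a3 <- .principal_axis(frame_coords(traj, f, i3))
    if (!is.null(prev2) && sum(a2 * prev2) < 0) a2 <- -a2
    if (!is.null(prev3) && sum(a3 * prev3) < 0) a3 <- -a3
    prev2 <- a2; prev3 <- a3
    ang[f] <- acos(max(-1, min(1, sum(a2 * a3)))) * 180 / pi
  }
  time_series("scissoring_angle", "deg", traj$times, ang)
}

#' Pearson coherence between two time series
#'
#' Product-moment correlation of the raw per-frame values (no smoothing,
#' no lag) — the "coherence" between, e.g., the 4-helix-bundle scissoring
#' coordinate and the minor-groove width modulation.
#'
#' @param a,b `ncp_series` of equal length >= 3 with nonzero variance.
#' @return Pearson correlation coefficient.
#' @export
series_correlation <- function(a, b) {
  x <- a$values; y <- b$values
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 frames")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance series has no defined correlation")
  }
  stats::cor(x, y)
}

#' Dominant harmonic amplitude of a series
#'
#' Estimates the amplitude of the strongest sinusoidal component: the
#' periodogram peak is located and the discrete Fourier magnitude is then
#' maximized over a continuous frequency neighbourhood of that bin
#' (avoiding scalloping loss when the oscillation period does not divide
#' the window). Used to recover planted breathing amplitudes from
#' end-to-dyad distance series.
#'
#' @param ts an `ncp_series`.
#' @return list with `amplitude` (same units as the series), `period`
#'   (in the series' time units) and `frequency` (cycles per time unit).
#' @export
harmonic_amplitude <- function(ts) {
  x <- ts$values - mean(ts$values)
  n <- length(x)
  if (n < 8L) stop("series too short for harmonic estimation")
  sp <- Mod(stats::fft(x))[2:floor(n / 2)]
  k0 <- which.max(sp)                       # cycles per window
  t_idx <- seq_len(n) - 1L
  dft_mag <- function(f) {
    ph <- -2 * pi * f * t_idx
    sqrt(sum(x * cos(ph))^2 + sum(x * sin(ph))^2)
  }
  opt <- stats::optimize(dft_mag, c((k0 - 1) / n, (k0 + 1) / n),
                         maximum = TRUE, tol = 1e-10)
  dt <- if (length(ts$times) > 1) ts$times[2] - ts$times[1] else 1
  freq <- opt$maximum / dt
  list(amplitude = 2 * opt$objective / n, period = 1 / freq,
       frequency = freq)
}
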
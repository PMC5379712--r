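#' @title Cell-biology counting and scoring rules
#' @name nucdyn-scoring
#' @description
#' Explicit counting rules for three microscopy readouts: chromatin-fiber
#' CENP-C co-localization, centromeric replication timing (EdU/CENP-B
#' double-positive foci), and four-category mitotic defect binning.
#' Inputs are already-scored tabular records; no image processing is
#' performed.
NULL

#' Score chromatin fibers for CENP-C co-localization
#'
#' A fiber is co-localization positive when the fraction of its tagged
#' CENP-A foci co-localizing with CENP-C reaches the threshold. The
#' inclusive comparison (`>=`, the default) follows the "at least 50%"
#' operational statement; a strict `>` mode is available because the two
#' phrasings circulate. Reported percentage is rounded to the nearest
#' integer; the exact fraction is returned alongside.
#'
#' @param records data frame with columns `fiber_id`, `n_spots` (>= 1),
#'   `n_coloc` (0 <= n_coloc <= n_spots).
#' @param threshold co-localized fraction defining a positive fiber
#'   (default 0.5).
#' @param strict use strictly-greater comparison (default FALSE).
#' @return list with `positive`, `total`, `percentage` (integer-rounded),
#'   `fraction`, and the per-fiber logical `is_positive`.
#' @export
score_fibers <- function(records, threshold = 0.5, strict = FALSE) {
  if (nrow(records) == 0L) stop("no fiber records")
  with(records, {
    if (any(n_spots < 1L)) stop("n_spots must be >= 1")
    if (any(n_coloc < 0L | n_coloc > n_spots)) {
      stop("n_coloc must lie in [0, n_spots]")
    }
  })
  frac <- records$n_coloc / records$n_spots
  pos <- if (strict) frac > threshold else frac >= threshold
  list(positive = sum(pos), total = nrow(records),
       percentage = round(100 * mean(pos)), fraction = mean(pos),
       is_positive = pos)
}

#' Centromeric replication fraction per cell-cycle phase
#'
#' Pooled convention: 100 x (sum of EdU+/CENP-B+ double-positive foci) /
#' (sum of CENP-B foci) over all cells of the phase — aggregate counts,
#' not the mean of per-cell ratios.
#'
#' @param counts data frame with columns `phase` (earlyS/midS/lateS),
#'   `n_cenpb`, `n_double` (0 <= n_double <= n_cenpb).
#' @param phase which phase to score.
#' @return percentage in [0, 100].
#' @export
replication_fraction <- function(counts, phase) {
  rows <- counts[counts$phase == phase, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no records for phase ", phase)
  if (any(rows$n_double < 0 | rows$n_double > rows$n_cenpb)) {
    stop("n_double must lie in [0, n_cenpb]")
  }
  tot <- sum(rows$n_cenpb)
  if (tot == 0) stop("zero total CENP-B foci in phase ", phase)
  100 * sum(rows$n_double) / tot
}

.mitotic_categories <- c("normal", "lagging", "multipolar",
                         "lagging+multipolar")

#' Classify anaphase cells into four mitotic-defect categories
#'
#' `(lagging, multipolar)` maps to: (F,F) normal, (T,F) lagging
#' chromosomes, (F,T) multipolar spindle, (T,T) lagging + multipolar.
#' Empty categories are reported as 0, never omitted; counts partition
#' the input and percentages sum to 100 within rounding.
#'
#' @param cells data frame with columns `cell_id`, `lagging`,
#'   `multipolar` (logical).
#' @return data frame with `category`, `count`, `percentage`.
#' @export
classify_mitoses <- function(cells) {
  if (nrow(cells) == 0L) stop("no cells to classify")
  cat_of <- ifelse(cells$lagging & cells$multipolar, "lagging+multipolar",
            ifelse(cells$lagging, "lagging",
            ifelse(cells$multipolar, "multipolar", "normal")))
  counts <- vapply(.mitotic_categories, function(k) sum(cat_of == k),
                   integer(1))
  data.frame(category = .mitotic_categories, count = unname(counts),
             percentage = unname(100 * counts / nrow(cells)),
             stringsAsFactors = FALSE)
}

#' Read scoring records from TSV
#'
#' Schemas (header row required): fibers `fiber_id n_spots n_coloc`;
#' replication `phase n_cenpb n_double`; mitosis `cell_id lagging
#' multipolar` (logical columns as TRUE/FALSE or 0/1).
#'
#' @param path TSV path.
#' @param kind `"fibers"`, `"replication"` or `"mitosis"`.
#' @return data frame validated against the schema.
#' @export
read_scoring_tsv <- function(path, kind = c("fibers", "replication",
                                            "mitosis")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- switch(kind,
    fibers = c("fiber_id", "n_spots", "n_coloc"),
    replication = c("phase", "n_cenpb", "n_double"),
    mitosis = c("cell_id", "lagging", "multipolar"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(kind, " TSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (kind == "mitosis") {
    df$lagging <- as.logical(df$lagging)
    df$multipolar <- as.logical(df$multipolar)
  }
  df
}

#' Generate synthetic scoring record tables with known ground truth
#'
#' Emits a fiber table with a prescribed number of positive fibers (all
#' foci co-localized) and negative fibers (none), a replication table
#' with prescribed pooled counts, or a mitosis table with prescribed
#' category counts — handy fixtures whose expected scores are known by
#' construction.
#'
#' @param kind record type.
#' @param ... for `fibers`: `n_positive`, `n_negative`, `spots_per_fiber`
#'   (default 4); for `replication`: `phase`, `n_cenpb`, `n_double`
#'   (vectors, one cell per element); for `mitosis`: named counts
#'   `normal`, `lagging`, `multipolar`, `both`.
#' @return data frame in the corresponding TSV schema.
#' @export
synthetic_scoring_records <- function(kind = c("fibers", "replication",
                                               "mitosis"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    fibers = {
      np <- args$n_positive; nn <- args$n_negative
      sp <- if (is.null(args$spots_per_fiber)) 4L else args$spots_per_fiber
      data.frame(fiber_id = seq_len(np + nn),
                 n_spots = sp,
                 n_coloc = c(rep(sp, np), rep(0L, nn)))
    },
    replication = {
      data.frame(phase = args$phase, n_cenpb = args$n_cenpb,
                 n_double = args$n_double, stringsAsFactors = FALSE)
    },
    mitosis = {
      n <- c(normal = args$normal, lagging = args$lagging,
             multipolar = args$multipolar, both = args$both)
      data.frame(cell_id = seq_len(sum(n)),
                 lagging = rep(c(FALSE, TRUE, FALSE, TRUE), n),
                 multipolar = rep(c(FALSE, FALSE, TRUE, TRUE), n))
    })
}
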
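#' Essential-dynamics PCA of a superposed trajectory
#'
#' Eigendecomposition of the 3N x 3N covariance (mass-unweighted) of the
#' selected coordinates. `scope = "core"` restricts to the Calpha beads of
#' the eight histone chains; `scope = "nuc"` adds the DNA phosphates with
#' `end_truncation_bp` base pairs dropped from each DNA end (ends have
#' high RMSF and would otherwise dominate the leading modes);
#' `scope = "custom"` uses `sel` as given. Eigenvalues are in Angstrom^2,
#' descending; eigenvector signs are fixed by making each vector's
#' largest-magnitude component positive so results are reproducible across
#' platforms.
#'
#' @param traj a superposed `ncp_trajectory` (>= 2 frames).
#' @param topo an `ncp_topology` (required for "core"/"nuc" scopes).
#' @param cfg an `ncp_config` (`end_truncation_bp` is used for "nuc").
#' @param scope `"core"`, `"nuc"` or `"custom"`.
#' @param sel selection for `scope = "custom"`.
#' @param n_modes number of leading modes for which projections are kept
#'   (default 10, capped at the rank).
#' @return object of class `ncp_pca` with `atom_idx`, `mean` (3N),
#'   `eigenvalues`, `eigenvectors` (3N x n_modes_kept, orthonormal),
#'   `projections` (frames x n_modes_kept), `total_variance`.
#' @export
pca_trajectory <- function(traj, topo = NULL, cfg = analysis_config(),
                           scope = c("core", "nuc", "custom"), sel = NULL,
                           n_modes = 10L) {
  scope <- match.arg(scope)
  if (traj$n_frames < 2L) stop("PCA needs at least 2 frames")
  histone_roles <- c("CENP-A", "CENP-A'", "H4", "H4'", "H2A", "H2A'",
                     "H2B", "H2B'")
  idx <- switch(scope,
    core = resolve_selection(selection(roles = histone_roles,
                                       atom_names = "CA"),
                             traj$structure, topo),
    nuc = {
      core <- resolve_selection(selection(roles = histone_roles,
                                          atom_names = "CA"),
                                traj$structure, topo)
      bp <- topo$basepair_map
      n_bp <- nrow(bp)
      tr <- cfg$end_truncation_bp
      if (n_bp - 2L * tr < 1L) stop("end truncation removes all base pairs")
      keep <- seq.int(tr + 1L, n_bp - tr)
      chain_I <- role_chain(topo, "DNA_I")
      chain_J <- role_chain(topo, "DNA_J")
      dna <- c(.atoms_of(traj$structure, chain_I, bp[keep, 1], "P"),
               .atoms_of(traj$structure, chain_J, bp[keep, 2], "P"))
      sort(c(core, dna))
    },
    custom = {
      if (is.null(sel)) stop("scope = 'custom' requires sel")
      resolve_selection(sel, traj$structure, topo)
    })
  X <- traj$xyz[, xyz_cols(idx), drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  keep_m <- min(as.integer(n_modes), ncol(C))
  V <- eig$vectors[, seq_len(keep_m), drop = FALSE]
  # sign convention: largest-magnitude component positive
  for (k in seq_len(keep_m)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  proj <- Xc %*% V
  structure(list(atom_idx = idx, mean = mu, eigenvalues = ev,
                 eigenvectors = V, projections = proj,
                 total_variance = sum(apply(X, 2, stats::var)),
                 scope = scope),
            class = "ncp_pca")
}

#' @export
print.ncp_pca <- function(x, ...) {
  vf <- if (sum(x$eigenvalues) > 0) x$eigenvalues[1] / sum(x$eigenvalues) else NA
  cat(sprintf("<ncp_pca> scope %s, %d atoms, PC1 %.1f%% of variance\n",
              x$scope, length(x$atom_idx), 100 * vf))
  invisible(x)
}

#' Free-energy landscape from mode projections
#'
#' 2D histogram of two mode projections converted to a free-energy
#' surface by Boltzmann inversion, `F = -kT ln(P / P_max)`, so the most
#' populated bin sits at exactly 0 and unsampled bins are flagged
#' (`NA` in `F`, FALSE in `sampled`) rather than assigned a value.
#'
#' @param x an `ncp_pca`, or a numeric matrix/data frame whose columns
#'   `mode_x` and `mode_y` are projection series.
#' @param mode_x,mode_y column (mode) indices (defaults 1 and 2).
#' @param n_bins number of bins per axis (>= 5, default 40).
#' @param kT energy unit (default 1; the surface is in kT).
#' @return object of class `ncp_fel` with `x_edges`, `y_edges`, `F`
#'   (n_bins x n_bins, kT), `sampled` (logical), `counts`, `kT`.
#' @export
free_energy_landscape <- function(x, mode_x = 1L, mode_y = 2L, n_bins = 40L,
                                  kT = 1.0) {
  proj <- if (inherits(x, "ncp_pca")) x$projections else as.matrix(x)
  if (max(mode_x, mode_y) > ncol(proj)) stop("mode index out of range")
  px <- proj[, mode_x]; py <- proj[, mode_y]
  if (n_bins < 5L) stop("n_bins must be >= 5")
  if (stats::sd(px) == 0 || stats::sd(py) == 0) {
    stop("degenerate (zero-variance) mode; no landscape")
  }
  xe <- seq(min(px), max(px), length.out = n_bins + 1L)
  ye <- seq(min(py), max(py), length.out = n_bins + 1L)
  ix <- pmin(findInterval(px, xe, rightmost.closed = TRUE), n_bins)
  iy <- pmin(findInterval(py, ye, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(ix, levels = seq_len(n_bins)),
               factor(iy, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  sampled <- counts > 0L
  F <- matrix(NA_real_, n_bins, n_bins)
  F[sampled] <- -kT * log(counts[sampled] / max(counts))
  structure(list(x_edges = xe, y_edges = ye, F = F, sampled = sampled,
                 counts = counts, kT = kT, modes = c(mode_x, mode_y)),
            class = "ncp_fel")
}

#' @export
print.ncp_fel <- function(x, ...) {
  cat(sprintf("<ncp_fel> %d x %d bins, %.1f%% sampled, max F %.3g kT\n",
              nrow(x$F), ncol(x$F), 100 * mean(x$sampled),
              max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Write a free-energy landscape as long-format TSV
#'
#' One row per bin: x_lo, x_hi, y_lo, y_hi, F_kT (empty for unsampled
#' bins), sampled flag.
#'
#' @param fel an `ncp_fel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fel <- function(fel, path) {
  nb <- nrow(fel$F)
  grid <- expand.grid(i = seq_len(nb), j = seq_len(nb))
  write_tsv(data.frame(
    x_lo = fel$x_edges[grid$i], x_hi = fel$x_edges[grid$i + 1L],
    y_lo = fel$y_edges[grid$j], y_hi = fel$y_edges[grid$j + 1L],
    F_kT = fel$F[cbind(grid$i, grid$j)],
    sampled = fel$sampled[cbind(grid$i, grid$j)]), path)
}

#' Export an amplified mode animation as a multi-MODEL PDB
#'
#' Frames trace the mean structure displaced along one eigenmode,
#' `mean + scale * sqrt(eigenvalue) * eigenvector * cos(phase)`, with the
#' phase sweeping one full cycle over `n_interp` frames; with an even
#' `n_interp` the extreme frames are displaced exactly
#' +/- scale * sqrt(eigenvalue). The default five-fold amplification
#' makes small collective motions visible.
#'
#' @param pcares an `ncp_pca`.
#' @param model the `ncp_structure` the PCA atoms belong to.
#' @param mode mode index (within the kept modes).
#' @param cfg an `ncp_config` (`animation_scale` is used).
#' @param n_interp frames per cycle (default 20; even recommended).
#' @param path optional output PDB path; if NULL nothing is written.
#' @return the animation as an `ncp_trajectory` over the PCA atoms,
#'   invisibly.
#' @export
export_mode_animation <- function(pcares, model, mode = 1L,
                                  cfg = analysis_config(), n_interp = 20L,
                                  path = NULL) {
  if (mode > ncol(pcares$eigenvectors)) stop("mode index out of range")
  amp <- cfg$animation_scale * sqrt(pcares$eigenvalues[mode])
  phase <- cos(2 * pi * (seq_len(n_interp) - 1L) / n_interp)
  v <- pcares$eigenvectors[, mode]
  xyz <- matrix(rep(pcares$mean, each = n_interp), n_interp) +
    outer(phase * amp, v)
  at <- model$atoms[pcares$atom_idx, , drop = FALSE]
  mean_co <- matrix(pcares$mean, ncol = 3L, byrow = TRUE)
  at$x <- mean_co[, 1]; at$y <- mean_co[, 2]; at$z <- mean_co[, 3]
  sub <- structure_model(at)
  anim <- trajectory(sub, xyz, seq_len(n_interp) - 1L,
                     metadata = list(mode = mode, scale = cfg$animation_scale))
  if (!is.null(path)) write_pdb(anim, path)
  invisible(anim)
}

#' Reconstruct superposed coordinates from all-mode projections
#'
#' Utility for the reconstruction identity: with all modes kept,
#' `mean + projections %*% t(eigenvectors)` reproduces the superposed
#' coordinates.
#'
#' @param pcares an `ncp_pca` computed with `n_modes` >= rank.
#' @return frames x 3N coordinate matrix.
#' @export
pca_reconstruct <- function(pcares) {
  sweep(tcrossprod(pcares$projections, pcares$eigenvectors), 2,
        pcares$mean, `+`)
}
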
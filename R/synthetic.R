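#' Simulation parameters for the synthetic nucleosome generator
#'
#' The generator is a statistical fixture, not a physics simulator: every
#' planted signal has an analytically known ground truth so downstream
#' analyses can be validated by parameter recovery. Defaults emulate a
#' 146-bp nucleosome core particle sampled at 0.1 ns per frame with
#' 0.5 Angstrom isotropic bead jitter, strongly asymmetric end breathing
#' (5 vs 1 Angstrom), and a scissoring/minor-groove latent oscillation
#' coupled at Pearson rho = 0.82.
#'
#' @param n_bp number of base pairs (default 146).
#' @param n_frames number of frames (default 5000).
#' @param frame_dt frame spacing in ns (default 0.1).
#' @param seed RNG seed recorded in trajectory metadata.
#' @param core_sigma per-bead isotropic Gaussian jitter SD, Angstrom
#'   (default 0.5; the "unmodified" regime).
#' @param core_sigma_acetyl jitter SD under the compacted "acetyl" regime
#'   (default 0.35).
#' @param entry_breathing_amp,exit_breathing_amp sinusoidal detachment
#'   amplitude of the terminal 10 bp at each DNA end, Angstrom
#'   (defaults 5 and 1 — the entry end breathes more).
#' @param entry_period_ns,exit_period_ns breathing periods in ns.
#' @param scissor_groove_rho target Pearson correlation in [-1, 1] between
#'   the alpha2-alpha3 scissoring coordinate and the minor-groove width
#'   modulation (default 0.82).
#' @param scissor_mean_deg resting alpha2-alpha3 angle, degrees (default 20).
#' @param scissor_sd_deg SD of the planted scissoring fluctuation, degrees
#'   (default 5).
#' @param groove_sd SD of the planted minor-groove width modulation,
#'   Angstrom (default 1.5).
#' @param dimer_com_shift rigid offset, Angstrom, moving the CENP-A'/H4'
#'   dimer toward CENP-A/H4 under the acetyl regime (default 2).
#' @param acetyl logical; use the compacted regime (acetyl jitter SD and
#'   the dimer COM shift).
#' @return object of class `ncp_sim_params`.
#' @export
simulation_params <- function(n_bp = 146L, n_frames = 5000L, frame_dt = 0.1,
                              seed = 1L,
                              core_sigma = 0.5, core_sigma_acetyl = 0.35,
                              entry_breathing_amp = 5, exit_breathing_amp = 1,
                              entry_period_ns = 40, exit_period_ns = 27,
                              scissor_groove_rho = 0.82,
                              scissor_mean_deg = 20, scissor_sd_deg = 5,
                              groove_sd = 1.5,
                              dimer_com_shift = 2.0,
                              acetyl = FALSE) {
  if (n_bp < 20L) stop("n_bp must be >= 20")
  if (n_frames < 10L) stop("n_frames must be >= 10")
  if (core_sigma < 0 || core_sigma_acetyl < 0) stop("sigmas must be >= 0")
  if (abs(scissor_groove_rho) > 1) stop("|scissor_groove_rho| must be <= 1")
  structure(as.list(environment()), class = "ncp_sim_params")
}

#' Preset parameter sets contrasting the two simulated regimes
#'
#' `"unmodified"` has symmetric moderate end breathing and no
#' scissoring-groove coupling; `"acetyl"` has the compacted core (smaller
#' jitter, dimer COM shift), asymmetric unwrapping and the coupled
#' scissoring-groove oscillation.
#'
#' @param preset `"unmodified"` or `"acetyl"`.
#' @param ... overrides passed to [simulation_params()].
#' @return an `ncp_sim_params`.
#' @export
preset_params <- function(preset = c("unmodified", "acetyl"), ...) {
  preset <- match.arg(preset)
  if (preset == "unmodified") {
    simulation_params(entry_breathing_amp = 2, exit_breathing_amp = 2,
                      scissor_groove_rho = 0, acetyl = FALSE, ...)
  } else {
    simulation_params(acetyl = TRUE, ...)
  }
}

# bead masses (Da): average nucleotide / average amino-acid residue
.dna_bead_mass <- 330.0
.histone_bead_mass <- 110.0

# 60-residue pseudo-histone chain layout (residue ranges)
.histone_segments <- list(
  alpha1 = 1:15, L1 = 16:20, alpha2 = 21:40, L2 = 41:45,
  alpha3 = 46:55, cterm = 56:60
)

.rot_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}

# beads of one straight segment: center + (k - mid) * 1.5 A along dir
.segment_beads <- function(center, dir, n) {
  dir <- dir / sqrt(sum(dir^2))
  k <- seq_len(n) - (n + 1) / 2
  sweep(outer(k * 1.5, dir), 2, center, `+`)
}

# per-chain segment geometry: list(segment -> list(center, dir))
.histone_layouts <- function(scissor_mean_deg) {
  a3dir_A <- as.vector(.rot_x(scissor_mean_deg) %*% c(0, 1, 0))
  a3dir_C <- as.vector(.rot_x(-scissor_mean_deg) %*% c(0, 1, 0))
  mk <- function(a1c, l1c, a2c, a2d, l2c, a3c, a3d, ctc) {
    list(alpha1 = list(a1c, c(1, 0, 0)), L1 = list(l1c, c(0, 1, 0)),
         alpha2 = list(a2c, a2d), L2 = list(l2c, c(1, 0, 0)),
         alpha3 = list(a3c, a3d), cterm = list(ctc, c(1, 0, 0)))
  }
  list(
    # CENP-A / CENP-A': alpha2 helices 6 A apart across the pseudo-dyad
    # axis (the 4-helix bundle); alpha3 tilted by the resting scissor angle
    "CENP-A"  = mk(c(-14, 0, -6), c(-9, 4, -3), c(-3, 0, 0), c(0, 1, 0),
                   c(-7, -4, 3), c(-10, 0, 3), a3dir_A, c(-15, -9, 6)),
    "CENP-A'" = mk(c(14, 0, 6), c(9, 4, 3), c(3, 0, 0), c(0, 1, 0),
                   c(7, -4, -3), c(10, 0, -3), a3dir_C, c(15, -9, -6)),
    "H4"   = mk(c(-22, 8, -10), c(-18, 12, -8), c(-20, 2, -12), c(0, 1, 0),
                c(-24, -2, -8), c(-26, 4, -14), c(0, 1, 0), c(-28, -6, -10)),
    "H4'"  = mk(c(22, 8, 10), c(18, 12, 8), c(20, 2, 12), c(0, 1, 0),
                c(24, -2, 8), c(26, 4, 14), c(0, 1, 0), c(28, -6, 10)),
    "H2A"  = mk(c(-4, 22, -14), c(0, 26, -12), c(2, 18, -16), c(1, 0, 0),
                c(6, 14, -12), c(8, 20, -18), c(1, 0, 0), c(10, 24, -14)),
    "H2B"  = mk(c(-4, 30, -20), c(0, 34, -18), c(2, 26, -22), c(1, 0, 0),
                c(6, 22, -18), c(8, 28, -24), c(1, 0, 0), c(10, 32, -20)),
    "H2A'" = mk(c(-4, -22, 14), c(0, -26, 12), c(2, -18, 16), c(1, 0, 0),
                c(6, -14, 12), c(8, -20, 18), c(1, 0, 0), c(10, -24, 14)),
    "H2B'" = mk(c(-4, -30, 20), c(0, -34, 18), c(2, -26, 22), c(1, 0, 0),
                c(6, -22, 18), c(8, -28, 24), c(1, 0, 0), c(10, -32, 20))
  )
}

#' Build an idealized pseudo-atomic nucleosome model
#'
#' Two antiparallel DNA strands of `n_bp` phosphate-like beads (name "P")
#' wound ~1.7 superhelical turns around eight 60-bead histone chains laid
#' out as four dimers; the CENP-A and CENP-A' alpha2 helices face each
#' other across the centre as an idealized 4-helix bundle. The topology
#' records the role map, the antiparallel base-pair map, the central base
#' pair as pseudo-dyad, and named segments (alpha2, alpha3, L1, cterm,
#' acidic_patch). Deterministic given the parameters.
#'
#' @param params an `ncp_sim_params`.
#' @return list with elements `model` (`ncp_structure`) and `topo`
#'   (`ncp_topology`).
#' @export
build_nucleosome_model <- function(params = simulation_params()) {
  stopifnot(inherits(params, "ncp_sim_params"))
  n_bp <- params$n_bp

  # superhelical path: 1.7 left-handed-ish turns, radius 41.8 A, pitch 25.9 A
  turns <- 1.7; R <- 41.8; pitch <- 25.9; r_h <- 9.3
  phi <- (seq_len(n_bp) - (n_bp + 1) / 2) / (n_bp - 1) * turns * 2 * pi
  centers <- cbind(R * cos(phi), R * sin(phi), pitch * phi / (2 * pi))
  # local frame: radial normal, tangent, binormal
  nrm <- cbind(cos(phi), sin(phi), 0)
  tng <- cbind(-R * sin(phi), R * cos(phi), pitch / (2 * pi))
  tng <- tng / sqrt(rowSums(tng^2))
  bnr <- cbind(tng[, 2] * nrm[, 3] - tng[, 3] * nrm[, 2],
               tng[, 3] * nrm[, 1] - tng[, 1] * nrm[, 3],
               tng[, 1] * nrm[, 2] - tng[, 2] * nrm[, 1])
  tau <- 2 * pi * seq_len(n_bp) / 10.5          # ~10.5 bp/turn local twist
  strand_I <- centers + r_h * (cos(tau) * nrm + sin(tau) * bnr)
  strand_J <- centers + r_h * (cos(tau + 2.4) * nrm + sin(tau + 2.4) * bnr)

  rows <- list()
  add <- function(pos, name, element, mass, chain, resno, resname) {
    data.frame(serial = NA_integer_, name = name, element = element,
               mass = mass, chain_id = chain, residue_index = resno,
               residue_name = resname,
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               stringsAsFactors = FALSE)
  }
  rows[["I"]] <- add(strand_I, "P", "P", .dna_bead_mass, "I",
                     seq_len(n_bp), "DN")
  # strand J runs antiparallel: its residue j pairs with strand-I residue
  # n_bp + 1 - j, and its beads are ordered by its own residue index
  j_res <- seq_len(n_bp)
  rows[["J"]] <- add(strand_J[n_bp + 1L - j_res, , drop = FALSE], "P", "P",
                     .dna_bead_mass, "J", j_res, "DN")

  layouts <- .histone_layouts(params$scissor_mean_deg)
  chain_ids <- c("CENP-A" = "A", "H4" = "B", "CENP-A'" = "C", "H4'" = "D",
                 "H2A" = "E", "H2B" = "F", "H2A'" = "G", "H2B'" = "H")
  for (role in names(chain_ids)) {
    lay <- layouts[[role]]
    pos <- do.call(rbind, lapply(names(.histone_segments), function(seg) {
      .segment_beads(lay[[seg]][[1]], lay[[seg]][[2]],
                     length(.histone_segments[[seg]]))
    }))
    rows[[role]] <- add(pos, "CA", "C", .histone_bead_mass, chain_ids[[role]],
                        unlist(.histone_segments, use.names = FALSE), "BEA")
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms)

  role_map <- c(stats::setNames(names(chain_ids), unname(chain_ids)),
                I = "DNA_I", J = "DNA_J")
  bp_map <- cbind(i = seq_len(n_bp), j = n_bp + 1L - seq_len(n_bp))
  dyad_i <- as.integer(ceiling(n_bp / 2))
  seg_rng <- lapply(.histone_segments, range)
  cterm_ranges <- list(
    "CENP-A" = seg_rng[c("alpha2", "alpha3", "L1", "cterm")],
    "CENP-A'" = seg_rng[c("alpha2", "alpha3", "L1", "cterm")],
    "H2A" = list(acidic_patch = c(36L, 42L)),
    "H2A'" = list(acidic_patch = c(36L, 42L))
  )
  topo <- nucleosome_topology(role_map, bp_map,
                              c(dyad_i, n_bp + 1L - dyad_i),
                              cterm_ranges, entry_end = "first")
  list(model = model, topo = topo)
}

# atom indices helper by chain + residues (+ name)
.atoms_of <- function(model, chain, residues = NULL, name = NULL) {
  at <- model$atoms
  keep <- at$chain_id == chain
  if (!is.null(residues)) keep <- keep & at$residue_index %in% residues
  if (!is.null(name)) keep <- keep & at$name == name
  which(keep)
}

#' Simulate a trajectory with planted, recoverable dynamics
#'
#' Frames are the reference structure plus four planted components:
#' (a) i.i.d. isotropic Gaussian jitter on every bead (SD `core_sigma`, or
#' `core_sigma_acetyl` under the acetyl regime) except the signal-carrying
#' beads below; (b) sinusoidal rigid displacement of the terminal 10 bp of
#' each DNA end along the dyad-to-end direction, with per-end amplitude and
#' period; (c) a latent bivariate-Gaussian oscillation driving both the
#' CENP-A alpha2-alpha3 scissoring angle (SD `scissor_sd_deg` about
#' `scissor_mean_deg`) and the minor-groove width at a probe base pair
#' (SD `groove_sd`), with correlation `scissor_groove_rho`; (d) under the
#' acetyl regime, a constant `dimer_com_shift` offset moving CENP-A'/H4'
#' toward CENP-A/H4. The CENP-A alpha2/alpha3 beads and the two groove
#' probe beads carry their deterministic signals without jitter so the
#' planted correlation and amplitudes have closed-form expectations.
#' Fully reproducible from `params$seed` (recorded in metadata).
#'
#' @param model,topo from [build_nucleosome_model()].
#' @param params an `ncp_sim_params`.
#' @return an `ncp_trajectory`.
#' @export
simulate_trajectory <- function(model, topo, params = simulation_params()) {
  stopifnot(inherits(params, "ncp_sim_params"))
  n_bp <- params$n_bp; nf <- params$n_frames
  na <- n_atoms(model)
  times <- (seq_len(nf) - 1L) * params$frame_dt
  sigma <- if (params$acetyl) params$core_sigma_acetyl else params$core_sigma

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  ref <- as.matrix(model$atoms[, c("x", "y", "z")])
  chain_A <- role_chain(topo, "CENP-A")
  a2_rng <- topo$cterm_ranges[["CENP-A"]][["alpha2"]]
  a3_rng <- topo$cterm_ranges[["CENP-A"]][["alpha3"]]
  idx_a3 <- .atoms_of(model, chain_A, a3_rng[1]:a3_rng[2])
  idx_a2 <- .atoms_of(model, chain_A, a2_rng[1]:a2_rng[2])

  # minor-groove probe: strand-I dyad residue and its +3-offset partner on J
  chain_I <- role_chain(topo, "DNA_I")
  chain_J <- role_chain(topo, "DNA_J")
  i_probe <- topo$dyad_pair[1]
  j_probe <- (n_bp + 1L - i_probe) + 3L
  idx_pI <- .atoms_of(model, chain_I, i_probe, "P")
  idx_pJ <- .atoms_of(model, chain_J, j_probe, "P")

  signal_idx <- c(idx_a2, idx_a3, idx_pI, idx_pJ)
  jitter_idx <- setdiff(seq_len(na), signal_idx)

  # (d) constant dimer offset under the acetyl regime
  if (params$acetyl && params$dimer_com_shift != 0) {
    grpA <- c(.atoms_of(model, chain_A), .atoms_of(model, role_chain(topo, "H4")))
    grpB <- c(.atoms_of(model, role_chain(topo, "CENP-A'")),
              .atoms_of(model, role_chain(topo, "H4'")))
    comA <- colSums(ref[grpA, , drop = FALSE] * model$atoms$mass[grpA]) /
      sum(model$atoms$mass[grpA])
    comB <- colSums(ref[grpB, , drop = FALSE] * model$atoms$mass[grpB]) /
      sum(model$atoms$mass[grpB])
    u <- (comA - comB) / sqrt(sum((comA - comB)^2))
    ref[grpB, ] <- sweep(ref[grpB, , drop = FALSE], 2,
                         params$dimer_com_shift * u, `+`)
  }

  xyz <- matrix(as.vector(t(ref)), nf, 3L * na, byrow = TRUE)

  # (a) isotropic jitter on non-signal beads
  if (sigma > 0) {
    cols <- xyz_cols(jitter_idx)
    xyz[, cols] <- xyz[, cols] + stats::rnorm(nf * length(cols), 0, sigma)
  }

  # (b) breathing: rigid sinusoidal displacement of the terminal 10 bp
  bp <- topo$basepair_map
  dyad_row <- which(bp[, 1] == topo$dyad_pair[1])
  end_rows <- list(first = 1:10, last = (n_bp - 9L):n_bp)
  ends <- if (topo$entry_end == "first") c(entry = "first", exit = "last")
          else c(entry = "last", exit = "first")
  amp <- c(entry = params$entry_breathing_amp, exit = params$exit_breathing_amp)
  per <- c(entry = params$entry_period_ns, exit = params$exit_period_ns)
  phs <- c(entry = 0, exit = 1.0)
  dyad_com <- (ref[.atoms_of(model, chain_I, bp[dyad_row, 1], "P"), ] +
               ref[.atoms_of(model, chain_J, bp[dyad_row, 2], "P"), ]) / 2
  for (e in c("entry", "exit")) {
    if (amp[[e]] == 0) next
    rows_e <- end_rows[[ends[[e]]]]
    term_row <- if (ends[[e]] == "first") 1L else n_bp
    end_com <- (ref[.atoms_of(model, chain_I, bp[term_row, 1], "P"), ] +
                ref[.atoms_of(model, chain_J, bp[term_row, 2], "P"), ]) / 2
    u <- (end_com - dyad_com) / sqrt(sum((end_com - dyad_com)^2))
    beads <- c(.atoms_of(model, chain_I, bp[rows_e, 1], "P"),
               .atoms_of(model, chain_J, bp[rows_e, 2], "P"))
    a_t <- amp[[e]] * sin(2 * pi * times / per[[e]] + phs[[e]])
    for (ax in 1:3) {
      cols <- 3L * (beads - 1L) + ax
      xyz[, cols] <- xyz[, cols] + tcrossprod(a_t, rep(u[ax], length(beads)))
    }
  }

  # (c) coupled scissoring / groove latent oscillation
  rho <- params$scissor_groove_rho
  z1 <- stats::rnorm(nf); z2 <- stats::rnorm(nf)
  s_t <- z1
  g_t <- rho * z1 + sqrt(max(0, 1 - rho^2)) * z2
  if (params$scissor_sd_deg > 0) {
    # rotate alpha3 about its centroid around the global x axis; alpha2 and
    # alpha3 axes lie in the yz plane so the inter-axis angle changes by
    # exactly the applied rotation
    cen <- colMeans(ref[idx_a3, , drop = FALSE])
    rel <- sweep(ref[idx_a3, , drop = FALSE], 2, cen)
    dth <- params$scissor_sd_deg * s_t * pi / 180
    # signed direction: positive opens the angle for the layout's +20 deg tilt
    cy <- cos(dth); sy <- sin(dth)
    ycols <- 3L * (idx_a3 - 1L) + 2L
    zcols <- 3L * (idx_a3 - 1L) + 3L
    xyz[, ycols] <- cen[2] + tcrossprod(cy, rel[, 2]) - tcrossprod(sy, rel[, 3])
    xyz[, zcols] <- cen[3] + tcrossprod(sy, rel[, 2]) + tcrossprod(cy, rel[, 3])
  }
  if (params$groove_sd > 0) {
    u <- ref[idx_pJ, ] - ref[idx_pI, ]
    u <- u / sqrt(sum(u^2))
    d_t <- params$groove_sd * g_t
    for (ax in 1:3) {
      xyz[, 3L * (idx_pJ - 1L) + ax] <-
        xyz[, 3L * (idx_pJ - 1L) + ax] + d_t * u[ax]
    }
  }

  trajectory(model, xyz, times,
             metadata = list(seed = params$seed,
                             regime = if (params$acetyl) "acetyl" else "unmodified",
                             core_sigma = sigma,
                             groove_probe_i = i_probe,
                             groove_probe_j = j_probe))
}
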
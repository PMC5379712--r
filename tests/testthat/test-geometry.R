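test_that("superposition removes rigid-body motion exactly", {
  set.seed(3)
  ref <- matrix(rnorm(30, sd = 8), 10)
  m <- fix_structure(ref)
  angles <- seq(0, 300, by = 20)
  shifts <- cbind(seq_along(angles), -seq_along(angles), 2)
  xyz <- t(vapply(seq_along(angles), function(k) {
    as.vector(t(sweep(ref %*% rot_z(angles[k]), 2, shifts[k, ], `+`)))
  }, numeric(30)))
  tr <- trajectory(m, xyz, seq_along(angles))
  sup <- superpose(tr)
  spread <- apply(sup$xyz, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-6)
  # idempotence: superposing an aligned trajectory changes nothing
  again <- superpose(sup)
  expect_equal(again$xyz, sup$xyz, tolerance = 1e-8)
})

test_that("superposition uses a proper rotation, never a reflection", {
  tetra <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4,
                  byrow = TRUE)
  m <- fix_structure(tetra)
  xyz <- rbind(as.vector(t(tetra)), as.vector(t(tetra %*% rot_z(90))))
  tr <- trajectory(m, xyz, 1:2)
  sup <- superpose(tr)
  # a reflection could also map the rotated frame onto the reference but
  # would invert chirality; the fitted frames must coincide
  expect_equal(frame_coords(sup, 1), frame_coords(sup, 2), tolerance = 1e-8)
  # degenerate (collinear) references are rejected
  line <- fix_structure(cbind(1:5, 0, 0))
  expect_error(superpose(fix_static_traj(line, 3)), "collinear")
})

test_that("RMSF matches hand-computable fixtures and blocking is sane", {
  m <- fix_structure(matrix(rnorm(15), 5))
  st <- fix_static_traj(m, 12)
  expect_equal(rmsf(st)$rmsf, rep(0, 5))
  # one atom alternating between two points distance d apart: RMSF = d/2
  d <- 3.2
  xyz <- matrix(rep(as.vector(t(m$atoms[, c("x", "y", "z")])), each = 12), 12)
  xyz[, 1] <- m$atoms$x[1] + rep(c(-d / 2, d / 2), 6)
  tr <- trajectory(m, xyz, 1:12)
  expect_equal(rmsf(tr)$rmsf[1], d / 2)
  r <- rmsf(tr, cfg = analysis_config(block_count = 3))
  expect_equal(dim(attr(r, "block_rmsf")), c(5L, 3L))
  expect_equal(unname(attr(r, "block_rmsf")[1, ]), rep(d / 2, 3))
  expect_equal(r$block_sd[1], 0)
  expect_error(rmsf(fix_static_traj(m, 2),
                    cfg = analysis_config(block_count = 3)),
               "fewer frames")
})

test_that("per-base-pair DNA RMSF averages the two strands", {
  dx <- fix_duplex(7)
  tr <- fix_static_traj(dx$model, 9)
  xyz <- tr$xyz
  # oscillate strand-I residue 3 (atom 3) and its partner (J residue 5,
  # atom index 7 + 5 = 12) with different amplitudes
  xyz[, 3 * 3 - 2] <- xyz[, 3 * 3 - 2] + rep(c(-1, 1, -1), 3)
  xyz[, 3 * 12 - 2] <- xyz[, 3 * 12 - 2] + rep(c(-2, 2, -2), 3)
  tr2 <- trajectory(dx$model, xyz, 1:9)
  r <- rmsf(tr2)
  bp <- rmsf_by_basepair(r, dx$topo)
  got <- bp$rmsf[bp$bp == 3]
  # two-point alternation with a 2:1 split across 9 frames
  v1 <- sqrt(mean((rep(c(-1, 1, -1), 3) - mean(rep(c(-1, 1, -1), 3)))^2))
  expect_equal(got, (v1 + 2 * v1) / 2)
})

test_that("COM distances are mass-weighted and symmetric in group order", {
  a <- fix_structure(matrix(c(0, 0, 0), 1), chain = "A")
  b <- fix_structure(matrix(c(3, 4, 0), 1), chain = "C")
  model <- fix_combine(a, b)
  topo <- nucleosome_topology(
    c(A = "CENP-A", C = "CENP-A'", I = "DNA_I", J = "DNA_J"),
    cbind(1L, 1L), c(1L, 1L))
  tr <- fix_static_traj(model, 4)
  selA <- selection(roles = "CENP-A"); selB <- selection(roles = "CENP-A'")
  res <- com_distance_series(tr, topo, selA, selB)
  expect_equal(res$series$values, rep(5, 4))
  expect_equal(res$summary$mean, 5)
  expect_equal(res$summary$variance, 0)
  sym <- com_distance_series(tr, topo, selB, selA)
  expect_equal(sym$series$values, res$series$values)
  # midpoint of two unit masses vs a remote single mass
  c2 <- fix_structure(rbind(c(0, 0, 0), c(2, 0, 0)), chain = "A")
  c1 <- fix_structure(matrix(c(5, 0, 0), 1), chain = "C")
  m2 <- fix_combine(c2, c1)
  res2 <- com_distance_series(fix_static_traj(m2, 3), topo, selA, selB)
  expect_equal(res2$summary$mean, 4)
})

test_that("end-to-dyad distances follow the duplex geometry", {
  dx <- fix_duplex(11)           # dyad at bp 6, ends at bp 1 and 11
  tr <- fix_static_traj(dx$model, 5)
  en <- dna_end_to_dyad_series(tr, dx$topo, "entry")
  ex <- dna_end_to_dyad_series(tr, dx$topo, "exit")
  expect_equal(en$series$values, rep(5 * 3.4, 5))   # |bp1 - bp6| = 5 rises
  expect_equal(ex$series$values, rep(5 * 3.4, 5))   # symmetric fixture
})

test_that("planted asymmetric breathing is recovered from end series", {
  sys <- fix_sim(n_frames = 2500, seed = 21)
  en <- dna_end_to_dyad_series(sys$traj, sys$topo, "entry")
  ex <- dna_end_to_dyad_series(sys$traj, sys$topo, "exit")
  expect_gt(en$summary$variance, ex$summary$variance)
  expect_equal(harmonic_amplitude(en$series)$amplitude, 5, tolerance = 0.1)
  expect_equal(harmonic_amplitude(ex$series)$amplitude, 1, tolerance = 0.1)
})

test_that("groove widths follow the P-P convention and isometry", {
  dx <- fix_duplex(11)
  # minor groove at position 4: partner is J residue (11+1-4)+3 = 11;
  # place that bead exactly 11.8 A from strand-I bead 4
  model <- dx$model
  p_i <- which(model$atoms$chain_id == "I" & model$atoms$residue_index == 4)
  p_j <- which(model$atoms$chain_id == "J" & model$atoms$residue_index == 11)
  target <- unlist(model$atoms[p_i, c("x", "y", "z")]) + c(0, -11.8, 0)
  model$atoms[p_j, c("x", "y", "z")] <- as.list(target)
  model <- structure_model(model$atoms)
  tr <- fix_static_traj(model, 4)
  w <- groove_width_series(tr, dx$topo, "minor", 4)
  expect_equal(w$values, rep(11.8 - 5.8, 4))
  # rigid rotation of every frame leaves widths unchanged
  R <- rot_z(37)
  xyz_rot <- t(apply(tr$xyz, 1, function(row) {
    as.vector(t(matrix(row, ncol = 3, byrow = TRUE) %*% R))
  }))
  w_rot <- groove_width_series(trajectory(model, xyz_rot, tr$times),
                               dx$topo, "minor", 4)
  expect_equal(w_rot$values, w$values, tolerance = 1e-10)
  # width floored at zero and off-strand offsets rejected
  expect_error(groove_width_series(tr, dx$topo, "major", 4), "runs off")
})

test_that("scissoring angle reads planted helix rotations", {
  # two parallel 10-bead lines -> 0 degrees
  a2 <- cbind(0, seq(0, 13.5, by = 1.5), 0)
  a3 <- sweep(a2, 2, c(5, 0, 0), `+`)
  sys0 <- fix_protein_system(
    list("CENP-A" = rbind(a2, a3)),
    cterm_ranges = list("CENP-A" = list(alpha2 = c(1, 10),
                                        alpha3 = c(11, 20))))
  s0 <- scissoring_series(fix_static_traj(sys0$model, 3), sys0$topo)
  expect_equal(s0$values, rep(0, 3), tolerance = 1e-8)
  # perpendicular lines -> 90 degrees
  a3p <- cbind(seq(0, 13.5, by = 1.5), 0, 3) + matrix(c(5, 7, 0), 20, 3,
                                                      byrow = TRUE)[1:10, ]
  sys90 <- fix_protein_system(
    list("CENP-A" = rbind(a2, a3p)),
    cterm_ranges = list("CENP-A" = list(alpha2 = c(1, 10),
                                        alpha3 = c(11, 20))))
  s90 <- scissoring_series(fix_static_traj(sys90$model, 3), sys90$topo)
  expect_equal(s90$values, rep(90, 3), tolerance = 1e-8)
  # planted sinusoid: open by 20 + 5 sin(wt) degrees about the x axis
  nf <- 240L
  theta <- 20 + 5 * sin(2 * pi * seq_len(nf) / 60)
  cen <- colMeans(a3)
  xyz <- t(vapply(theta, function(th) {
    rel <- sweep(a3, 2, cen)
    a3r <- sweep(rel %*% t(rot_x(th)), 2, cen, `+`)
    as.vector(t(rbind(a2, a3r, matrix(c(500, 0, 0, 500, 5, 0), 2,
                                      byrow = TRUE))))
  }, numeric(66)))
  trs <- trajectory(sys0$model, xyz, seq_len(nf))
  ss <- scissoring_series(trs, sys0$topo)
  expect_equal(mean(ss$values), 20, tolerance = 0.02)
  expect_equal(harmonic_amplitude(ss)$amplitude, 5, tolerance = 0.1)
  # helices shorter than 4 residues are rejected
  sys_short <- fix_protein_system(
    list("CENP-A" = rbind(a2, a3)),
    cterm_ranges = list("CENP-A" = list(alpha2 = c(1, 2),
                                        alpha3 = c(11, 20))))
  expect_error(scissoring_series(fix_static_traj(sys_short$model, 3),
                                 sys_short$topo), "fewer than 4")
})

test_that("Pearson coherence behaves on exact and degenerate inputs", {
  a <- time_series("a", "A", 1:50, sin(1:50))
  expect_equal(series_correlation(a, a), 1.0)
  neg <- time_series("b", "A", 1:50, -sin(1:50))
  expect_equal(series_correlation(a, neg), -1.0)
  flat <- time_series("c", "A", 1:50, rep(2, 50))
  expect_error(series_correlation(a, flat), "zero-variance")
  short <- time_series("d", "A", 1:2, c(1, 2))
  expect_error(series_correlation(short, short), "at least 3")
})

test_that("harmonic amplitude estimation resists spectral leakage", {
  set.seed(8)
  n <- 2000
  x <- 3.7 * sin(2 * pi * 12.37 * seq_len(n) / n + 0.4) + rnorm(n, sd = 0.3)
  ts <- time_series("x", "A", seq_len(n) * 0.1, x)
  est <- harmonic_amplitude(ts)
  expect_equal(est$amplitude, 3.7, tolerance = 0.02)
  expect_equal(est$period, n * 0.1 / 12.37, tolerance = 0.01)
})
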
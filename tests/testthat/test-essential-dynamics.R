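# small planted-mode trajectory: ref + a_t * v + noise
planted_mode_traj <- function(n_atoms = 100L, n_frames = 600L, amp = 3,
                              noise_sd = 0.01, seed = 1L) {
  set.seed(seed)
  ref <- matrix(rnorm(n_atoms * 3, sd = 10), n_atoms)
  v <- rnorm(n_atoms * 3); v <- v / sqrt(sum(v^2))
  a_t <- amp * sin(2 * pi * seq_len(n_frames) / 97)
  xyz <- matrix(rep(as.vector(t(ref)), each = n_frames), n_frames) +
    outer(a_t, v) + matrix(rnorm(n_frames * n_atoms * 3, sd = noise_sd),
                           n_frames)
  list(traj = trajectory(fix_structure(ref), xyz, seq_len(n_frames)), v = v)
}

sel_all <- selection(atom_names = "CA")

test_that("static trajectories have zero eigenvalues; trace identity holds", {
  m <- fix_structure(matrix(rnorm(60), 20))
  pc0 <- pca_trajectory(fix_static_traj(m, 10), scope = "custom",
                        sel = sel_all)
  expect_equal(pc0$eigenvalues, rep(0, 60))
  pm <- planted_mode_traj(n_atoms = 30, n_frames = 200)
  pc <- pca_trajectory(pm$traj, scope = "custom", sel = sel_all, n_modes = 90)
  expect_equal(sum(pc$eigenvalues), pc$total_variance, tolerance = 1e-10)
  # orthonormal eigenvectors, and mean projects to zero
  G <- crossprod(pc$eigenvectors)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8)
  expect_equal(colMeans(pc$projections), rep(0, ncol(pc$projections)),
               tolerance = 1e-10)
})

test_that("a planted collective mode is recovered as PC1", {
  pm <- planted_mode_traj()
  pc <- pca_trajectory(pm$traj, scope = "custom", sel = sel_all)
  expect_gt(abs(sum(pc$eigenvectors[, 1] * pm$v)), 0.99)
  expect_gt(pc$eigenvalues[1] / sum(pc$eigenvalues), 0.95)
})

test_that("projection onto all modes reconstructs the coordinates", {
  pm <- planted_mode_traj(n_atoms = 15, n_frames = 120, noise_sd = 0.3)
  pc <- pca_trajectory(pm$traj, scope = "custom", sel = sel_all, n_modes = 45)
  rec <- pca_reconstruct(pc)
  expect_lt(max(abs(rec - pm$traj$xyz)), 1e-6)
})

test_that("PCA scopes select histone cores and truncated DNA", {
  sys <- fix_sim(n_frames = 40)
  sup <- superpose(sys$traj)
  pc_core <- pca_trajectory(sup, sys$topo, scope = "core")
  expect_equal(length(pc_core$atom_idx), 8L * 60L)
  pc_nuc <- pca_trajectory(sup, sys$topo, analysis_config(), scope = "nuc")
  # 10 bp truncated from each end on both strands
  expect_equal(length(pc_nuc$atom_idx), 8L * 60L + 2L * (146L - 20L))
  at <- sys$model$atoms[pc_nuc$atom_idx, ]
  expect_true(all(at$residue_index[at$chain_id == "I"] %in% 11:136))
})

test_that("free-energy landscapes invert sampling probability", {
  set.seed(5)
  proj <- cbind(rnorm(1e4, sd = 2), rnorm(1e4, sd = 1))
  fel <- free_energy_landscape(proj, n_bins = 30)
  expect_equal(min(fel$F, na.rm = TRUE), 0)
  expect_true(all(fel$F[fel$sampled] >= 0))
  expect_true(all(is.na(fel$F[!fel$sampled])))
  expect_equal(sum(fel$counts), 1e4)
  # two point masses: the heavy bin has F = 0, the light one kT ln(ratio)
  pts <- cbind(c(rep(0, 60), rep(10, 20)), c(rep(0, 60), rep(10, 20)))
  fel2 <- free_energy_landscape(pts, n_bins = 5)
  sampled_F <- sort(fel2$F[fel2$sampled])
  expect_equal(sampled_F, c(0, log(3)))
  expect_equal(sum(fel2$sampled), 2L)
  # degenerate input rejected
  expect_error(free_energy_landscape(cbind(rep(1, 50), rnorm(50))),
               "degenerate")
})

test_that("Boltzmann inversion recovers Gaussian curvature", {
  set.seed(11)
  sx <- 2; sy <- 1
  proj <- cbind(rnorm(1e5, sd = sx), rnorm(1e5, sd = sy))
  fel <- free_energy_landscape(proj, n_bins = 40)
  xc <- (fel$x_edges[-1] + fel$x_edges[-41]) / 2
  yc <- (fel$y_edges[-1] + fel$y_edges[-41]) / 2
  grid <- expand.grid(x = xc, y = yc)
  ok <- as.vector(fel$sampled)
  fit <- lm(F ~ I(x^2) + I(y^2) + x + y,
            data = cbind(grid, F = as.vector(fel$F))[ok, ],
            weights = as.vector(fel$counts)[ok])
  expect_equal(unname(coef(fit)["I(x^2)"]), 1 / (2 * sx^2), tolerance = 0.15)
  expect_equal(unname(coef(fit)["I(y^2)"]), 1 / (2 * sy^2), tolerance = 0.15)
})

test_that("mode animations trace the amplified eigenmode", {
  pm <- planted_mode_traj(n_atoms = 40, n_frames = 300, noise_sd = 0.02)
  pc <- pca_trajectory(pm$traj, scope = "custom", sel = sel_all)
  cfg5 <- analysis_config(animation_scale = 5)
  anim <- export_mode_animation(pc, pm$traj$structure, 1, cfg5,
                                n_interp = 8)
  disp <- sweep(anim$xyz, 2, pc$mean)
  amps <- as.vector(disp %*% pc$eigenvectors[, 1])
  expect_equal(max(amps), 5 * sqrt(pc$eigenvalues[1]), tolerance = 1e-8)
  expect_equal(min(amps), -5 * sqrt(pc$eigenvalues[1]), tolerance = 1e-8)
  # off-mode displacement is zero: frames move only along the mode
  resid <- disp - outer(amps, pc$eigenvectors[, 1])
  expect_lt(max(abs(resid)), 1e-8)
  # scale 0 collapses onto the mean structure
  anim0 <- export_mode_animation(pc, pm$traj$structure, 1,
                                 analysis_config(animation_scale = 0),
                                 n_interp = 4)
  expect_equal(max(abs(sweep(anim0$xyz, 2, pc$mean))), 0)
  # round trip: PCA of the animation recovers the same direction
  pc2 <- pca_trajectory(anim, scope = "custom", sel = sel_all, n_modes = 2)
  expect_gt(abs(sum(pc2$eigenvectors[, 1] * pc$eigenvectors[, 1])), 0.999)
  # multi-MODEL PDB export is readable frame by frame
  f <- withr::local_tempfile(fileext = ".pdb")
  export_mode_animation(pc, pm$traj$structure, 1, cfg5, n_interp = 4,
                        path = f)
  m3 <- read_pdb(f, model = 3)
  expect_equal(n_atoms(m3), 40L)
  expect_error(read_pdb(f, model = 9), "no MODEL")
  expect_error(export_mode_animation(pc, pm$traj$structure, 99), "out of range")
})
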
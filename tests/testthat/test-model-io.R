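test_that("PDB reading preserves identity, chain order and coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY B   2       4.000   5.000   6.000  1.00  0.00           C",
    "END"), f)
  m <- read_pdb(f)
  expect_equal(n_atoms(m), 2L)
  expect_equal(m$chains, c("A", "B"))
  expect_equal(unlist(m$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))
  expect_equal(m$atoms$residue_index, c(1L, 2L))
  # element column absent: inferred from atom name, mass attached
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("ATOM      1  P   DN  I   1       0.000   0.000   0.000", f2)
  m2 <- read_pdb(f2)
  expect_equal(m2$atoms$element, "P")
  expect_equal(m2$atoms$mass, 30.973762)
})

test_that("malformed and duplicate PDB records raise located errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
    "ATOM      2  CA  ALA A   2       1.0"), f)
  expect_error(read_pdb(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000"), f2)
  expect_error(read_pdb(f2), "duplicate")
  expect_error(read_pdb(withr::local_tempfile()), "no such file")
})

test_that("PDB read agrees with an independent reader on a written model", {
  sys <- fix_sim(n_frames = 10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys$model, f)
  ours <- read_pdb(f)
  ref <- bio3d::read.pdb(f, verbose = FALSE)
  expect_equal(nrow(ref$atom), n_atoms(ours))
  expect_equal(unname(as.numeric(ref$atom$x)), ours$atoms$x)
  expect_equal(unname(ref$atom$chain), ours$atoms$chain_id)
  expect_equal(unname(ref$atom$resno), ours$atoms$residue_index)
})

test_that("trajectory round trip through .trj is the identity to precision", {
  m <- fix_structure(matrix(rnorm(6), 2))
  tr <- trajectory(m, matrix(rnorm(18), 3), c(0, 0.1, 0.2),
                   metadata = list(seed = 1))
  f <- withr::local_tempfile(fileext = ".trj")
  write_trj(tr, f)
  back <- read_trj(f, m)
  expect_equal(back$n_frames, 3L)
  expect_equal(back$xyz, round(tr$xyz, 6), tolerance = 1e-12)
  expect_equal(back$times, tr$times)
  expect_equal(back$metadata$seed, 1)
})

test_that("a frame with a missing atom is reported by frame number", {
  sys <- fix_sim(n_frames = 10, n_bp = 20)
  f <- withr::local_tempfile(fileext = ".trj")
  write_trj(sys$traj, f)
  lines <- readLines(f)
  frame2 <- grep("^frame 2 ", lines)
  writeLines(lines[-(frame2 + 1L)], f)
  expect_error(read_trj(f, sys$model), "frame 2")
  # atom-count mismatch against the structure is also caught
  expect_error(read_trj(f, fix_structure(matrix(0, 2, 3))), "atom count")
})

test_that("equilibration truncation keeps the final window and composes", {
  m <- fix_structure(matrix(rnorm(9), 3))
  xyz <- matrix(rnorm(1000 * 9), 1000)
  tr <- trajectory(m, xyz, seq_len(1000))
  cut <- apply_equilibration(tr, analysis_config(equilibration_fraction = 0.6))
  expect_equal(cut$n_frames, 400L)
  expect_equal(cut$times, 601:1000)
  expect_equal(cut$xyz[1, ], xyz[601, ])
  # fraction 0 is the identity, and truncating again changes nothing
  same <- apply_equilibration(tr, analysis_config(equilibration_fraction = 0))
  expect_equal(same$xyz, tr$xyz)
  twice <- apply_equilibration(cut, analysis_config(equilibration_fraction = 0))
  expect_equal(twice$xyz, cut$xyz)
  small <- trajectory(m, xyz[1:10, ], 1:10)
  expect_error(
    apply_equilibration(small, analysis_config(equilibration_fraction = 0.95)),
    "need >= 2")
})

test_that("selections resolve deterministically, reject empties, and union
           concatenates without duplicates", {
  sys <- fix_sim(n_frames = 10)
  idx <- resolve_selection(selection(roles = "CENP-A", atom_names = "CA"),
                           sys$model, sys$topo)
  at <- sys$model$atoms[idx, ]
  expect_true(all(at$chain_id == "A" & at$name == "CA"))
  expect_equal(sum(sys$model$atoms$chain_id == "A"), length(idx))
  expect_equal(idx, sort(idx))  # file order
  expect_error(
    resolve_selection(selection(roles = "CENP-A", residue_range = c(900, 999)),
                      sys$model, sys$topo),
    "zero atoms")
  a <- selection(roles = "CENP-A", residue_range = c(1, 10))
  b <- selection(roles = "CENP-A", residue_range = c(5, 20))
  u <- resolve_selection(list(a, b), sys$model, sys$topo)
  expect_equal(anyDuplicated(u), 0L)
  expect_equal(sort(u),
               resolve_selection(selection(roles = "CENP-A",
                                           residue_range = c(1, 20)),
                                 sys$model, sys$topo))
  expect_error(resolve_selection(selection(roles = "CENP-Z"),
                                 sys$model, sys$topo), "not present")
})

test_that("structure and topology invariants are enforced", {
  at <- data.frame(serial = 1:2, name = "CA", element = "C", mass = 110,
                   chain_id = "A", residue_index = 1L, residue_name = "BEA",
                   x = 0, y = 0, z = 0)
  expect_error(structure_model(at), "duplicate")
  at$mass <- c(110, -1); at$residue_index <- 1:2
  expect_error(structure_model(at), "mass")
  expect_error(nucleosome_topology(c(I = "DNA_I", J = "DNA_J"),
                                   cbind(c(1, 2), c(2, 2)), c(1, 2)),
               "bijection")
  expect_error(nucleosome_topology(c(I = "DNA_I", J = "DNA_J"),
                                   cbind(c(1, 2), c(1, 2)), c(1, 1)),
               "antiparallel")
  expect_error(nucleosome_topology(c(I = "DNA_I", J = "DNA_J"),
                                   cbind(c(1, 2), c(2, 1)), c(1, 1)),
               "dyad_pair")
  expect_error(nucleosome_topology(c(I = "DNA_I"),
                                   cbind(1, 1), c(1, 1)),
               "DNA_J")
})

test_that("topology YAML round trip preserves all fields", {
  sys <- fix_sim(n_frames = 10)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_topology(sys$topo, f)
  back <- read_topology(f)
  expect_equal(back$role_map[order(names(back$role_map))],
               sys$topo$role_map[order(names(sys$topo$role_map))])
  expect_equal(back$basepair_map, sys$topo$basepair_map)
  expect_equal(back$dyad_pair, sys$topo$dyad_pair)
  expect_equal(back$entry_end, sys$topo$entry_end)
  expect_equal(back$cterm_ranges[["CENP-A"]][["alpha2"]],
               as.integer(sys$topo$cterm_ranges[["CENP-A"]][["alpha2"]]))
})
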
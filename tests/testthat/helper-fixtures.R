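# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# structure from a coordinate matrix (one chain, one atom per residue)
fix_structure <- function(coords, chain = "X", name = "CA", element = "C",
                          mass = 110, first_res = 1L) {
  n <- nrow(coords)
  structure_model(data.frame(
    serial = seq_len(n), name = name, element = element, mass = mass,
    chain_id = chain, residue_index = seq.int(first_res, first_res + n - 1L),
    residue_name = "BEA", x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

# combine several ncp_structures into one (chains must differ)
fix_combine <- function(...) {
  atoms <- do.call(rbind, lapply(list(...), function(s) s$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms)
}

# trajectory replicating the reference structure in every frame
fix_static_traj <- function(model, n_frames = 5L, dt = 1) {
  ref <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- matrix(rep(as.vector(t(ref)), each = n_frames), n_frames)
  trajectory(model, xyz, (seq_len(n_frames) - 1L) * dt)
}

# straight rigid duplex: strand I bead i at (i*rise, +1, 0), strand J bead
# with residue j at ((n+1-j)*rise, -1, 0) so base pair i sits at x = i*rise
fix_duplex <- function(n_bp = 11L, rise = 3.4) {
  i_co <- cbind(seq_len(n_bp) * rise, 1, 0)
  j_res <- seq_len(n_bp)
  j_co <- cbind((n_bp + 1L - j_res) * rise, -1, 0)
  dI <- fix_structure(i_co, chain = "I", name = "P", element = "P", mass = 330)
  dJ <- fix_structure(j_co, chain = "J", name = "P", element = "P", mass = 330)
  model <- fix_combine(dI, dJ)
  dyad_i <- as.integer(ceiling(n_bp / 2))
  topo <- nucleosome_topology(
    role_map = c(I = "DNA_I", J = "DNA_J"),
    basepair_map = cbind(i = seq_len(n_bp), j = n_bp + 1L - seq_len(n_bp)),
    dyad_pair = c(dyad_i, n_bp + 1L - dyad_i))
  list(model = model, topo = topo)
}

# protein-only mini system (dummy 1-bp duplex satisfies the topology
# contract); chains: named list role -> coordinate matrix
fix_protein_system <- function(chains, cterm_ranges = list()) {
  ids <- c("CENP-A" = "A", "CENP-A'" = "C", "H4" = "B", "H4'" = "D",
           "H2A" = "E", "H2A'" = "G", "H2B" = "F", "H2B'" = "H")
  parts <- lapply(names(chains), function(role) {
    fix_structure(chains[[role]], chain = ids[[role]])
  })
  dI <- fix_structure(matrix(c(500, 0, 0), 1), chain = "I", name = "P",
                      element = "P", mass = 330)
  dJ <- fix_structure(matrix(c(500, 5, 0), 1), chain = "J", name = "P",
                      element = "P", mass = 330)
  model <- do.call(fix_combine, c(parts, list(dI, dJ)))
  role_map <- stats::setNames(names(chains), unname(ids[names(chains)]))
  role_map <- c(role_map, I = "DNA_I", J = "DNA_J")
  topo <- nucleosome_topology(role_map, cbind(i = 1L, j = 1L), c(1L, 1L),
                              cterm_ranges)
  list(model = model, topo = topo)
}

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}

# small quiet simulation for pipeline tests
fix_sim <- function(n_frames = 200L, seed = 1L, ...) {
  p <- simulation_params(n_frames = n_frames, seed = seed, ...)
  sys <- build_nucleosome_model(p)
  list(params = p, model = sys$model, topo = sys$topo,
       traj = simulate_trajectory(sys$model, sys$topo, p))
}
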
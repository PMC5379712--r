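#' @title Domain model: structures, trajectories, topology, selections
#' @name nucdyn-model
#' @description
#' The package represents an atomic (or pseudo-atomic) structure as an
#' ordered atom table, a trajectory as a frames-by-3N coordinate matrix,
#' and the nucleosome architecture (chain roles, base pairing, pseudo-dyad,
#' named segments) as a topology object. Coordinates are Angstrom
#' throughout, times are nanoseconds, frames are indexed from 1 and residue
#' indices are kept exactly as given by the input (1-based in PDB files) —
#' they are never renumbered.
NULL

# Average atomic masses (Da) used when attaching masses per element at read
# time; pseudo-atoms from the synthetic generator carry explicit masses.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762,
  S = 32.06, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  `NA` = 22.98976928, K = 39.0983, CL = 35.45, MN = 54.938043, CA = 40.078
)

#' Element mass lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of average atomic masses in Da.
#' @export
element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Construct a structure model
#'
#' An ordered table of atoms with chain/residue identity, masses and
#' reference coordinates.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `mass` (Da), `chain_id`, `residue_index`, `residue_name`, `x`, `y`,
#'   `z` (Angstrom).
#' @return object of class `ncp_structure` with elements `atoms` and
#'   `chains` (unique chain ids in file order).
#' @export
structure_model <- function(atoms) {
  required <- c("serial", "name", "element", "mass", "chain_id",
                "residue_index", "residue_name", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("all atom masses must be finite and > 0")
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("all atom positions must be finite")
  }
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom-name) triple: ",
         key[anyDuplicated(key)])
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chains = unique(atoms$chain_id)),
            class = "ncp_structure")
}

#' @export
print.ncp_structure <- function(x, ...) {
  cat(sprintf("<ncp_structure> %d atoms, %d chains (%s)\n",
              nrow(x$atoms), length(x$chains),
              paste(x$chains, collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a structure or trajectory
#' @param x an `ncp_structure` or `ncp_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "ncp_trajectory")) x <- x$structure
  nrow(x$atoms)
}

#' Construct a trajectory
#'
#' @param structure an `ncp_structure`.
#' @param xyz numeric matrix, `n_frames` rows by `3 * n_atoms` columns,
#'   columns grouped as (x1, y1, z1, x2, ...), Angstrom.
#' @param times numeric vector of per-frame timestamps in ns, strictly
#'   increasing.
#' @param metadata optional named list (e.g. generator seed) carried along.
#' @return object of class `ncp_trajectory`.
#' @export
trajectory <- function(structure, xyz, times, metadata = list()) {
  stopifnot(inherits(structure, "ncp_structure"))
  xyz <- as.matrix(xyz)
  na <- nrow(structure$atoms)
  if (ncol(xyz) != 3L * na) {
    stop(sprintf("coordinate matrix has %d columns; expected 3 x %d atoms = %d",
                 ncol(xyz), na, 3L * na))
  }
  if (nrow(xyz) < 1L) stop("trajectory needs at least one frame")
  if (length(times) != nrow(xyz)) stop("length(times) must equal frame count")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (any(!is.finite(xyz))) stop("trajectory coordinates must be finite")
  structure(list(structure = structure, xyz = xyz, times = as.numeric(times),
                 n_frames = nrow(xyz), metadata = metadata),
            class = "ncp_trajectory")
}

#' @export
print.ncp_trajectory <- function(x, ...) {
  cat(sprintf("<ncp_trajectory> %d frames x %d atoms, t = [%.4g, %.4g] ns\n",
              x$n_frames, n_atoms(x), x$times[1], x$times[x$n_frames]))
  invisible(x)
}

#' Per-frame coordinates of selected atoms
#'
#' @param traj an `ncp_trajectory`.
#' @param frame frame index (1-based).
#' @param idx atom indices (default all).
#' @return numeric matrix `length(idx)` x 3.
#' @export
frame_coords <- function(traj, frame, idx = seq_len(n_atoms(traj))) {
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  matrix(traj$xyz[frame, cols], ncol = 3L, byrow = TRUE)
}

#' Column indices into the xyz matrix for a set of atoms
#' @keywords internal
xyz_cols <- function(idx) {
  as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}

.nucleosome_roles <- c("CENP-A", "CENP-A'", "H4", "H4'", "H2A", "H2A'",
                       "H2B", "H2B'", "DNA_I", "DNA_J", "CENP-C", "CENP-C'")

#' Construct a nucleosome topology
#'
#' Assigns chains to nucleosome roles and records the DNA base-pair map,
#' the pseudo-dyad base pair and named residue segments (C-terminus,
#' helices, acidic patch, ...).
#'
#' @param role_map named character vector: names are chain ids, values are
#'   roles among `r paste(.nucleosome_roles, collapse = ", ")`.
#' @param basepair_map two-column integer matrix; column `i` holds strand-I
#'   residue indices (ascending), column `j` the paired strand-J residue
#'   indices. Strand-J indices must decrease as strand-I indices increase
#'   (the duplex is antiparallel) and the map must be a bijection.
#' @param dyad_pair length-2 integer vector `(i, j)`, one row of
#'   `basepair_map`, designated the pseudo-dyad.
#' @param cterm_ranges nested named list: role -> segment name ->
#'   `c(first, last)` residue indices (e.g. CENP-A "cterm", "alpha2",
#'   "alpha3", "L1"; H2A "acidic_patch").
#' @param entry_end which DNA end is the entry side: `"first"` (strand-I
#'   5' terminus, the default) or `"last"`.
#' @return object of class `ncp_topology`.
#' @export
nucleosome_topology <- function(role_map, basepair_map, dyad_pair,
                                cterm_ranges = list(),
                                entry_end = c("first", "last")) {
  entry_end <- match.arg(entry_end)
  bad <- setdiff(unname(role_map), .nucleosome_roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  for (dna_role in c("DNA_I", "DNA_J")) {
    if (sum(role_map == dna_role) != 1L) {
      stop("role ", dna_role, " must map to exactly one chain")
    }
  }
  basepair_map <- as.matrix(basepair_map)
  colnames(basepair_map) <- c("i", "j")
  if (anyDuplicated(basepair_map[, 1]) || anyDuplicated(basepair_map[, 2])) {
    stop("basepair_map must be a bijection")
  }
  o <- order(basepair_map[, 1])
  basepair_map <- basepair_map[o, , drop = FALSE]
  if (nrow(basepair_map) > 1L && any(diff(basepair_map[, 2]) >= 0)) {
    stop("strand-J indices must decrease as strand-I indices increase (antiparallel)")
  }
  hit <- which(basepair_map[, 1] == dyad_pair[1] &
               basepair_map[, 2] == dyad_pair[2])
  if (length(hit) != 1L) stop("dyad_pair is not an entry of basepair_map")
  structure(list(role_map = role_map, basepair_map = basepair_map,
                 dyad_pair = as.integer(dyad_pair),
                 cterm_ranges = cterm_ranges, entry_end = entry_end),
            class = "ncp_topology")
}

#' @export
print.ncp_topology <- function(x, ...) {
  cat(sprintf("<ncp_topology> %d chains, %d base pairs, dyad (%d, %d), entry end: %s\n",
              length(x$role_map), nrow(x$basepair_map),
              x$dyad_pair[1], x$dyad_pair[2], x$entry_end))
  invisible(x)
}

#' Chain id carrying a given role
#' @param topo an `ncp_topology`.
#' @param role role name.
#' @return chain id string.
#' @export
role_chain <- function(topo, role) {
  hit <- names(topo$role_map)[topo$role_map == role]
  if (length(hit) == 0L) stop("role not present in topology: ", role)
  hit
}

#' Atom selection by role, residue range and atom name
#'
#' A declarative predicate resolved against a structure + topology into a
#' deterministic, file-ordered atom index list.
#'
#' @param roles character vector of nucleosome roles (NULL = any chain).
#' @param residue_range `c(first, last)` residue indices (NULL = any).
#' @param atom_names character vector of atom names (NULL = any).
#' @return object of class `ncp_selection`.
#' @export
selection <- function(roles = NULL, residue_range = NULL, atom_names = NULL) {
  if (!is.null(residue_range) && length(residue_range) != 2L) {
    stop("residue_range must be c(first, last)")
  }
  structure(list(roles = roles, residue_range = residue_range,
                 atom_names = atom_names), class = "ncp_selection")
}

#' Resolve a selection to atom indices
#'
#' @param sel an `ncp_selection`, or a list of them (resolved in order and
#'   concatenated without duplicates).
#' @param model an `ncp_structure`.
#' @param topo an `ncp_topology` (may be NULL if `sel` names no roles).
#' @return integer vector of atom indices in file order (per selection),
#'   never empty.
#' @export
resolve_selection <- function(sel, model, topo = NULL) {
  if (inherits(sel, "ncp_selection")) sel <- list(sel)
  idx <- integer(0)
  for (s in sel) {
    at <- model$atoms
    keep <- rep(TRUE, nrow(at))
    if (!is.null(s$roles)) {
      if (is.null(topo)) stop("selection names roles but no topology given")
      chains <- unlist(lapply(s$roles, role_chain, topo = topo))
      keep <- keep & at$chain_id %in% chains
    }
    if (!is.null(s$residue_range)) {
      keep <- keep & at$residue_index >= s$residue_range[1] &
              at$residue_index <= s$residue_range[2]
    }
    if (!is.null(s$atom_names)) keep <- keep & at$name %in% s$atom_names
    this <- which(keep)
    if (length(this) == 0L) {
      stop("selection resolves to zero atoms (roles: ",
           paste(s$roles, collapse = ","), "; residues: ",
           paste(s$residue_range, collapse = "-"), "; names: ",
           paste(s$atom_names, collapse = ","), ")")
    }
    idx <- c(idx, this)
  }
  idx[!duplicated(idx)]
}

#' Analysis configuration
#'
#' Bundles the knobs shared across analysis stages. Defaults follow common
#' practice for microsecond-scale nucleosome runs: drop the first 60% of
#' frames as extended equilibration, count an 8 Angstrom representative-atom
#' distance as a contact, report blocked statistics over thirds, drop ten
#' base pairs from each DNA end before whole-nucleosome PCA, and amplify
#' exported mode animations five-fold.
#'
#' @param equilibration_fraction fraction of leading frames discarded
#'   before analysis (default 0.6).
#' @param contact_cutoff contact distance cutoff in Angstrom (default 8).
#' @param block_count number of contiguous blocks for blocked statistics
#'   (default 3).
#' @param end_truncation_bp base pairs dropped from each DNA end for
#'   whole-nucleosome PCA (default 10).
#' @param animation_scale mode-amplification factor for exported
#'   animations (default 5).
#' @param kT energy unit for free-energy landscapes (default 1; landscapes
#'   are reported in kT).
#' @return object of class `ncp_config`.
#' @export
analysis_config <- function(equilibration_fraction = 0.6,
                            contact_cutoff = 8.0,
                            block_count = 3L,
                            end_truncation_bp = 10L,
                            animation_scale = 5,
                            kT = 1.0) {
  if (equilibration_fraction < 0 || equilibration_fraction >= 1) {
    stop("equilibration_fraction must be in [0, 1)")
  }
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  if (block_count < 2) stop("block_count must be >= 2")
  if (end_truncation_bp < 0) stop("end_truncation_bp must be >= 0")
  structure(list(equilibration_fraction = equilibration_fraction,
                 contact_cutoff = contact_cutoff,
                 block_count = as.integer(block_count),
                 end_truncation_bp = as.integer(end_truncation_bp),
                 animation_scale = animation_scale, kT = kT),
            class = "ncp_config")
}

#' Discard the equilibration window of a trajectory
#'
#' Removes the first `floor(equilibration_fraction * n_frames)` frames;
#' timestamps of retained frames are preserved. With the default fraction
#' of 0.6 a 1000-frame run keeps its final 400 frames, mirroring analysis
#' of the final 400 ns of a 1 microsecond production run.
#'
#' @param traj an `ncp_trajectory`.
#' @param cfg an `ncp_config` (only `equilibration_fraction` is used).
#' @return the truncated `ncp_trajectory`.
#' @export
apply_equilibration <- function(traj, cfg = analysis_config()) {
  drop_n <- floor(cfg$equilibration_fraction * traj$n_frames)
  keep <- seq.int(drop_n + 1L, traj$n_frames)
  if (length(keep) < 2L) {
    stop(sprintf("equilibration fraction %.3g leaves %d frame(s); need >= 2",
                 cfg$equilibration_fraction, length(keep)))
  }
  trajectory(traj$structure, traj$xyz[keep, , drop = FALSE],
             traj$times[keep], traj$metadata)
}
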
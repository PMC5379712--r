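#' Residue-residue contact occupancy over a trajectory
#'
#' Each residue is represented by a single representative atom (Calpha for
#' protein, P for DNA, enforced by the selections); the occupancy of a
#' residue pair is the fraction of analyzed frames in which the
#' representative-atom distance is less than or equal to the cutoff
#' (a distance exactly at the cutoff counts as a contact). Occupancy 1
#' means the contact is formed in every frame, 0 never. The trajectory is
#' analyzed on its equilibration-truncated window.
#'
#' @param traj an `ncp_trajectory`.
#' @param topo an `ncp_topology`.
#' @param selA,selB selections resolving to exactly one representative
#'   atom per residue.
#' @param cfg an `ncp_config`; `contact_cutoff` and
#'   `equilibration_fraction` are used.
#' @param equilibrate apply the equilibration truncation first (default
#'   TRUE; set FALSE if `traj` is already the analysis window).
#' @return object of class `ncp_contact_map` with `occupancy` matrix,
#'   `row_residues` / `col_residues` (role, residue_index tables),
#'   `cutoff`, `n_frames_used`.
#' @export
contact_occupancy <- function(traj, topo, selA, selB,
                              cfg = analysis_config(), equilibrate = TRUE) {
  if (equilibrate && cfg$equilibration_fraction > 0) {
    traj <- apply_equilibration(traj, cfg)
  }
  ra <- .residue_representatives(traj$structure, topo, selA)
  rb <- .residue_representatives(traj$structure, topo, selB)
  nf <- traj$n_frames
  occ <- matrix(0, nrow(ra), ncol = nrow(rb))
  cut2 <- cfg$contact_cutoff^2
  for (f in seq_len(nf)) {
    A <- frame_coords(traj, f, ra$atom)
    B <- frame_coords(traj, f, rb$atom)
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    occ <- occ + (d2 <= cut2 + 1e-9)
  }
  occ <- occ / nf
  dimnames(occ) <- list(paste0(ra$role, ":", ra$residue_index),
                        paste0(rb$role, ":", rb$residue_index))
  structure(list(occupancy = occ,
                 row_residues = ra[, c("role", "residue_index")],
                 col_residues = rb[, c("role", "residue_index")],
                 cutoff = cfg$contact_cutoff, n_frames_used = nf),
            class = "ncp_contact_map")
}

# one representative atom per residue of a selection; errors on 0 or >1
.residue_representatives <- function(model, topo, sel) {
  idx <- resolve_selection(sel, model, topo)
  at <- model$atoms[idx, , drop = FALSE]
  key <- paste(at$chain_id, at$residue_index)
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    stop("residue with multiple representative atoms in selection: ", bad)
  }
  chain_role <- stats::setNames(unname(topo$role_map), names(topo$role_map))
  data.frame(atom = idx, role = unname(chain_role[at$chain_id]),
             residue_index = at$residue_index, stringsAsFactors = FALSE)
}

#' @export
print.ncp_contact_map <- function(x, ...) {
  cat(sprintf("<ncp_contact_map> %d x %d residues, cutoff %.3g A, %d frames; mean occupancy %.3f\n",
              nrow(x$occupancy), ncol(x$occupancy), x$cutoff,
              x$n_frames_used, mean(x$occupancy)))
  invisible(x)
}

#' Interface retention: mean occupancy and stable contacts
#'
#' A residue pair is a "stable contact" if its occupancy is at least
#' `threshold` (default 0.5).
#'
#' @param map an `ncp_contact_map`.
#' @param threshold occupancy fraction defining stability.
#' @return list with `mean_occupancy`, and `stable` (data frame of pairs
#'   with occupancy >= threshold, with their occupancies).
#' @export
interface_retention <- function(map, threshold = 0.5) {
  occ <- map$occupancy
  hit <- which(occ >= threshold, arr.ind = TRUE)
  stable <- data.frame(
    row = rownames(occ)[hit[, 1]], col = colnames(occ)[hit[, 2]],
    occupancy = occ[hit], stringsAsFactors = FALSE)
  stable <- stable[order(-stable$occupancy, stable$row, stable$col), ]
  rownames(stable) <- NULL
  list(mean_occupancy = mean(occ), stable = stable)
}

#' Compare two contact maps over the same residue axes
#'
#' Classifies residue pairs as retained, lost or gained between a
#' reference map and a comparison map, judged at a stability threshold
#' (e.g. the unmodified vs acetylated CENP-C docking interface).
#'
#' @param ref,cmp `ncp_contact_map`s with identical residue axes.
#' @param threshold stability threshold (default 0.5).
#' @return list of data frames `retained`, `lost`, `gained` (pair labels
#'   with both occupancies).
#' @export
compare_contact_maps <- function(ref, cmp, threshold = 0.5) {
  if (!identical(dimnames(ref$occupancy), dimnames(cmp$occupancy))) {
    stop("contact maps have mismatched residue axes")
  }
  a <- ref$occupancy >= threshold
  b <- cmp$occupancy >= threshold
  pick <- function(mask) {
    hit <- which(mask, arr.ind = TRUE)
    out <- data.frame(row = rownames(a)[hit[, 1]], col = colnames(a)[hit[, 2]],
                      occupancy_ref = ref$occupancy[hit],
                      occupancy_cmp = cmp$occupancy[hit],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$row, out$col), ]
  }
  list(retained = pick(a & b), lost = pick(a & !b), gained = pick(!a & b))
}

#' Per-frame count of residue pairs in contact
#'
#' @inheritParams contact_occupancy
#' @return an `ncp_series` (counts per frame). Its mean equals the sum of
#'   the corresponding occupancy matrix.
#' @export
contact_count_series <- function(traj, topo, selA, selB,
                                 cfg = analysis_config(), equilibrate = TRUE) {
  if (equilibrate && cfg$equilibration_fraction > 0) {
    traj <- apply_equilibration(traj, cfg)
  }
  ra <- .residue_representatives(traj$structure, topo, selA)
  rb <- .residue_representatives(traj$structure, topo, selB)
  cut2 <- cfg$contact_cutoff^2
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    A <- frame_coords(traj, f, ra$atom)
    B <- frame_coords(traj, f, rb$atom)
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    sum(d2 <= cut2 + 1e-9)
  }, numeric(1))
  time_series("contact_count", "pairs", traj$times, vals)
}

#' Write a contact map as TSV with labeled axes
#'
#' @param map an `ncp_contact_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  df <- as.data.frame(map$occupancy)
  df <- cbind(residue = rownames(map$occupancy), df)
  write_tsv(df, path)
}
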
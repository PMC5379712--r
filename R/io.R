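#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records (fixed-width columns). The element is taken
#' from columns 77-78 when present, otherwise inferred from the atom-name
#' columns. Per-element average masses are attached at read time since PDB
#' files carry none.
#'
#' @param path path to a PDB file.
#' @param model which MODEL to read when the file holds several (default 1).
#' @return an `ncp_structure`.
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts)) {
    if (model > length(model_starts)) stop("file has no MODEL ", model)
    from <- model_starts[model]
    ends <- which(trimws(rec) == "ENDMDL")
    to <- min(ends[ends > from], length(lines))
    keep_range <- seq.int(from, to)
  } else {
    keep_range <- seq_along(lines)
  }
  is_atom <- keep_range[rec[keep_range] %in% c("ATOM  ", "HETATM")]
  if (!length(is_atom)) stop("no ATOM/HETATM records in ", path)

  parse_one <- function(i) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("PDB parse error at line %d: record shorter than coordinate columns", i))
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      stop(sprintf("PDB parse error at line %d: unreadable coordinates", i))
    }
    serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (is.na(serial) || is.na(resno)) {
      stop(sprintf("PDB parse error at line %d: unreadable serial/residue number", i))
    }
    name <- trimws(substr(ln, 13, 16))
    elem <- trimws(substr(ln, 77, 78))
    if (elem == "") {
      # infer from atom name: leading digits stripped, first alpha char(s);
      # two-letter elements in protein/DNA context are rare — take the first
      # letter unless the name starts in column 13 with a two-letter symbol
      nm <- gsub("[0-9']", "", name)
      elem <- toupper(substr(nm, 1, 1))
    }
    list(serial = serial, name = name, element = toupper(elem),
         chain_id = trimws(substr(ln, 22, 22)),
         residue_index = resno,
         residue_name = trimws(substr(ln, 18, 20)),
         x = xyz[1], y = xyz[2], z = xyz[3])
  }
  parsed <- lapply(is_atom, parse_one)
  atoms <- data.frame(
    serial = vapply(parsed, `[[`, integer(1), "serial"),
    name = vapply(parsed, `[[`, character(1), "name"),
    element = vapply(parsed, `[[`, character(1), "element"),
    mass = NA_real_,
    chain_id = vapply(parsed, `[[`, character(1), "chain_id"),
    residue_index = vapply(parsed, `[[`, integer(1), "residue_index"),
    residue_name = vapply(parsed, `[[`, character(1), "residue_name"),
    x = vapply(parsed, `[[`, numeric(1), "x"),
    y = vapply(parsed, `[[`, numeric(1), "y"),
    z = vapply(parsed, `[[`, numeric(1), "z"),
    stringsAsFactors = FALSE
  )
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$name)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate (chain, residue, atom) at line %d: %s",
                 is_atom[dup[1]], key[dup[1]]))
  }
  atoms$mass <- element_mass(atoms$element)
  structure_model(atoms)
}

.format_pdb_atom <- function(a) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          a$serial %% 100000L,
          ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
          substr(a$residue_name, 1, 3), substr(a$chain_id, 1, 1),
          a$residue_index %% 10000L, a$x, a$y, a$z, substr(a$element, 1, 2))
}

#' Write a structure (or trajectory, as multi-MODEL) to PDB
#'
#' @param x an `ncp_structure`, or an `ncp_trajectory` written as one
#'   MODEL per frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "ncp_structure")) {
    writeLines(.format_pdb_atom(x$atoms), con)
    writeLines("END", con)
  } else if (inherits(x, "ncp_trajectory")) {
    at <- x$structure$atoms
    for (f in seq_len(x$n_frames)) {
      co <- frame_coords(x, f)
      at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
      writeLines(sprintf("MODEL %8d", f), con)
      writeLines(.format_pdb_atom(at), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    stop("x must be an ncp_structure or ncp_trajectory")
  }
  invisible(path)
}

#' Write a trajectory in the native plain-text .trj format
#'
#' The format is deliberately human-diffable: a header with the atom and
#' frame counts plus optional metadata lines, then per frame a
#' `frame <k> time <ns>` line followed by one `x y z` triple per atom.
#'
#' @param traj an `ncp_trajectory`.
#' @param path output path.
#' @param digits coordinate precision (default 6 significant-after-point).
#' @return `path`, invisibly.
#' @export
write_trj <- function(traj, path, digits = 6L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nucdyn-trj 1", con)
  writeLines(sprintf("natoms %d", n_atoms(traj)), con)
  writeLines(sprintf("nframes %d", traj$n_frames), con)
  for (key in names(traj$metadata)) {
    writeLines(sprintf("meta %s %s", key, format(traj$metadata[[key]])), con)
  }
  fmt <- sprintf("%%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("frame %d time %.6f", f, traj$times[f]), con)
    co <- frame_coords(traj, f)
    writeLines(sprintf(fmt, co[, 1], co[, 2], co[, 3]), con)
  }
  invisible(path)
}

#' Read a native plain-text .trj trajectory
#'
#' @param path path to a `.trj` file written by [write_trj()].
#' @param structure the `ncp_structure` the frames belong to; the per-frame
#'   atom count must match.
#' @return an `ncp_trajectory`.
#' @export
read_trj <- function(path, structure) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (!length(ln)) stop(".trj header lacks '", key, "'")
    as.integer(strsplit(ln[1], "\\s+")[[1]][2])
  }
  na <- hdr("natoms"); nf <- hdr("nframes")
  if (na != n_atoms(structure)) {
    stop(sprintf(".trj atom count %d does not match structure (%d atoms)",
                 na, n_atoms(structure)))
  }
  meta_lines <- grep("^meta ", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    parts <- strsplit(ml, "\\s+")[[1]]
    val <- paste(parts[-(1:2)], collapse = " ")
    num <- suppressWarnings(as.numeric(val))
    metadata[[parts[2]]] <- if (is.na(num)) val else num
  }
  frame_at <- grep("^frame ", lines)
  if (length(frame_at) != nf) {
    stop(sprintf(".trj declares %d frames but contains %d 'frame' lines",
                 nf, length(frame_at)))
  }
  times <- numeric(nf)
  xyz <- matrix(NA_real_, nf, 3L * na)
  bounds <- c(frame_at, length(lines) + 1L)
  for (f in seq_len(nf)) {
    parts <- strsplit(lines[frame_at[f]], "\\s+")[[1]]
    times[f] <- as.numeric(parts[4])
    body <- lines[seq.int(frame_at[f] + 1L, bounds[f + 1L] - 1L)]
    if (length(body) != na) {
      stop(sprintf("frame %d has %d atom lines; expected %d",
                   f, length(body), na))
    }
    vals <- scan(text = body, quiet = TRUE)
    if (length(vals) != 3L * na) {
      stop(sprintf("frame %d: could not read %d coordinate triples", f, na))
    }
    xyz[f, ] <- vals
  }
  trajectory(structure, xyz, times, metadata)
}

#' Write / read a nucleosome topology as YAML
#'
#' @param topo an `ncp_topology`.
#' @param path output path.
#' @return `path` invisibly (write); an `ncp_topology` (read).
#' @export
write_topology <- function(topo, path) {
  obj <- list(
    role_map = as.list(topo$role_map),
    basepair_i = as.integer(topo$basepair_map[, 1]),
    basepair_j = as.integer(topo$basepair_map[, 2]),
    dyad_pair = as.integer(topo$dyad_pair),
    entry_end = topo$entry_end,
    cterm_ranges = lapply(topo$cterm_ranges, function(segs) {
      lapply(segs, as.integer)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- yaml::read_yaml(path)
  nucleosome_topology(
    role_map = unlist(obj$role_map),
    basepair_map = cbind(i = obj$basepair_i, j = obj$basepair_j),
    dyad_pair = obj$dyad_pair,
    cterm_ranges = lapply(obj$cterm_ranges, function(segs) {
      lapply(segs, as.integer)
    }),
    entry_end = obj$entry_end
  )
}

#' Write a data frame as TSV with a header row
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
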
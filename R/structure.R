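#' Build a C-alpha structure model
#'
#' A structure model is the unit all geometry in remdguide operates on: an
#' ordered set of residues, one C-alpha position each, coordinates in
#' nanometres. It is a tibble with columns `res_id`, `res_name`, `x`, `y`,
#' `z` and a `label` attribute, so it pipes straight into dplyr verbs.
#'
#' @param coords Numeric matrix, one row per residue, three columns (nm).
#' @param res_id Integer vector of 1-based residue positions, strictly
#'   increasing. Defaults to `1:nrow(coords)`.
#' @param res_name Character vector of 3-letter residue codes (default
#'   `"ALA"`).
#' @param label Free-text label carried through analyses.
#' @return A `structure_model` tibble.
#' @examples
#' structure_model(matrix(c(0, 0, 0, 0.38, 0, 0), 2, 3, byrow = TRUE))
#' @export
structure_model <- function(coords, res_id = seq_len(nrow(coords)),
                            res_name = "ALA", label = "structure") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) abort("`coords` must have three columns (x, y, z).")
  m <- tibble(
    res_id = as.integer(res_id),
    res_name = rep_len(as.character(res_name), nrow(coords)),
    x = as.numeric(coords[, 1]),
    y = as.numeric(coords[, 2]),
    z = as.numeric(coords[, 3])
  )
  new_structure_model(m, label)
}

new_structure_model <- function(df, label = "structure") {
  out <- as_tibble(df)[, c("res_id", "res_name", "x", "y", "z")]
  attr(out, "label") <- label
  class(out) <- c("structure_model", class(tibble()))
  validate_structure_model(out)
}

validate_structure_model <- function(m) {
  if (nrow(m) == 0) abort("structure model has no residues.")
  if (any(diff(m$res_id) <= 0)) {
    abort("`res_id` must be strictly increasing (one C-alpha per residue).")
  }
  bad <- !is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z)
  if (any(bad)) {
    abort(sprintf("non-finite coordinates at residue(s) %s.",
                  paste(m$res_id[bad], collapse = ", ")))
  }
  m
}

#' @rdname structure_model
#' @param x Object to test or coerce.
#' @export
is_structure_model <- function(x) inherits(x, "structure_model")

#' @rdname structure_model
#' @export
as_structure_model <- function(x, label = "structure") {
  if (is_structure_model(x)) return(x)
  need <- c("res_id", "x", "y", "z")
  if (!all(need %in% names(x))) {
    abort("need columns res_id, x, y, z (plus optional res_name).")
  }
  if (is.null(x$res_name)) x$res_name <- "ALA"
  new_structure_model(x, label)
}

# n x 3 coordinate matrix (nm)
coords_matrix <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

# flat xyz vector in bio3d order (x1, y1, z1, x2, ...), Angstrom
xyz_flat_ang <- function(model) {
  as.numeric(t(coords_matrix(model))) * 10
}

#' Read a C-alpha structure from a PDB file
#'
#' Reads ATOM records, keeps one C-alpha per residue (first altLoc
#' occurrence wins) and converts coordinates from Angstrom to nanometres.
#'
#' @param path Path to a PDB file containing CA atoms.
#' @param chain_policy `"merge"` (default) concatenates all chains in file
#'   order and renumbers residues consecutively from 1, mirroring how
#'   multi-chain systems are treated as one molecule in a single topology;
#'   `"single"` keeps the first chain only.
#' @return A [structure_model()].
#' @seealso [write_structure()]
#' @export
read_structure <- function(path, chain_policy = c("merge", "single")) {
  chain_policy <- match.arg(chain_policy)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) abort(sprintf(
                    "could not parse PDB file %s: %s", path, conditionMessage(e))))
  atoms <- pdb$atom
  if (nrow(atoms) == 0) abort(sprintf("no ATOM records in %s", path))
  res_key <- paste(atoms$chain, atoms$resno)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) abort(sprintf("no CA atoms in %s", path))
  # first altLoc occurrence per (chain, residue)
  ca <- ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]
  missing_ca <- setdiff(unique(res_key), paste(ca$chain, ca$resno))
  if (length(missing_ca) > 0) {
    abort(sprintf("residue(s) without a CA atom: %s",
                  paste(missing_ca, collapse = ", ")))
  }
  if (chain_policy == "single") {
    first_chain <- ca$chain[1]
    ca <- ca[ca$chain %in% first_chain, , drop = FALSE]
  }
  structure_model(
    coords = cbind(ca$x, ca$y, ca$z) / 10,
    res_id = seq_len(nrow(ca)),
    res_name = ca$resid,
    label = basename(path)
  )
}

#' Write a C-alpha structure to a PDB file
#'
#' Emits standard ATOM records (CA only, occupancy 1.00), converting the
#' model's nanometre coordinates back to Angstrom. `read_structure()`
#' after `write_structure()` recovers the coordinates within PDB precision
#' (1e-3 Angstrom).
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  model <- as_structure_model(model)
  xyz_ang <- xyz_flat_ang(model)
  if (any(abs(xyz_ang) > 9999)) {
    abort("coordinates exceed 9999 Angstrom; PDB fixed-width fields overflow.")
  }
  n <- nrow(model)
  bio3d::write.pdb(
    file = path, xyz = xyz_ang,
    resno = model$res_id, resid = model$res_name,
    elety = rep("CA", n), o = rep(1, n), b = rep(0, n)
  )
  invisible(path)
}

#' Read a C-alpha trajectory
#'
#' Accepts either a multi-model PDB (MODEL/ENDMDL blocks) or a plain
#' whitespace-delimited frame table with columns
#' `frame_index time_ns res_id x y z` (coordinates in nm). The result is a
#' long tibble: one row per residue per frame.
#'
#' @param path File to read.
#' @param format `"auto"` (default, by extension/content), `"pdb"` or
#'   `"table"`.
#' @param time_step_ns Frame spacing used when the file carries no times
#'   (PDB input).
#' @param temperature Optional temperature label (K) for the ensemble.
#' @return A `trajectory_ensemble` tibble with columns
#'   `frame`, `time_ns`, `res_id`, `res_name`, `x`, `y`, `z`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "table"),
                            time_step_ns = 1, temperature = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^(MODEL|ATOM|HEADER|REMARK|TITLE|CRYST)", first))
      "pdb" else "table"
  }
  if (format == "pdb") {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
    ca_idx <- which(pdb$atom$elety == "CA")
    if (length(ca_idx) == 0) abort("no CA atoms in trajectory PDB.")
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    n_frames <- nrow(xyz)
    cols <- as.integer(t(outer(ca_idx - 1, 1:3, function(a, k) 3 * a + k)))
    frames <- purrr::map(seq_len(n_frames), function(f) {
      co <- matrix(xyz[f, cols], ncol = 3, byrow = TRUE) / 10
      tibble(
        frame = f, time_ns = (f - 1) * time_step_ns,
        res_id = seq_along(ca_idx),
        res_name = pdb$atom$resid[ca_idx],
        x = co[, 1], y = co[, 2], z = co[, 3]
      )
    })
    out <- dplyr::bind_rows(frames)
  } else {
    tab <- utils::read.table(path, header = FALSE, col.names =
      c("frame_index", "time_ns", "res_id", "x", "y", "z"))
    out <- tibble(
      frame = as.integer(tab$frame_index), time_ns = tab$time_ns,
      res_id = as.integer(tab$res_id), res_name = "ALA",
      x = tab$x, y = tab$y, z = tab$z
    )
  }
  new_trajectory(out, temperature = temperature)
}

new_trajectory <- function(df, temperature = NA_real_) {
  out <- as_tibble(df)
  counts <- dplyr::count(out, .data$frame)
  if (length(unique(counts$n)) > 1) {
    abort("frames have inconsistent residue counts.")
  }
  ids <- dplyr::distinct(out, .data$frame, .data$res_id)
  per_frame <- split(ids$res_id, ids$frame)
  if (length(unique(lapply(per_frame, identity))) > 1 &&
      !all(purrr::map_lgl(per_frame, identical, per_frame[[1]]))) {
    abort("frames do not share an identical residue set.")
  }
  times <- dplyr::distinct(out, .data$frame, .data$time_ns)
  if (any(diff(times$time_ns[order(times$frame)]) <= 0) && nrow(times) > 1) {
    abort("frame times must be strictly increasing.")
  }
  attr(out, "temperature") <- temperature
  class(out) <- unique(c("trajectory_ensemble", class(tibble())))
  out
}

#' @rdname read_trajectory
#' @param traj A `trajectory_ensemble` tibble.
#' @export
write_trajectory <- function(traj, path, format = c("table", "pdb")) {
  format <- match.arg(format)
  if (format == "table") {
    tab <- traj[, c("frame", "time_ns", "res_id", "x", "y", "z")]
    utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in unique(traj$frame)) {
      fr <- traj[traj$frame == f, ]
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        fr$res_id, substr(fr$res_name, 1, 3), fr$res_id,
        fr$x * 10, fr$y * 10, fr$z * 10), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

# split a trajectory into a list of structure_model, one per frame
trajectory_frames <- function(traj) {
  purrr::map(split(as_tibble(traj), traj$frame), function(fr) {
    structure_model(cbind(fr$x, fr$y, fr$z), res_id = fr$res_id,
                    res_name = fr$res_name,
                    label = sprintf("frame %d", fr$frame[1]))
  })
}

# assemble a trajectory from a list of structure models
trajectory_from_frames <- function(frames, times = seq_along(frames) - 1,
                                   temperature = NA_real_) {
  rows <- purrr::imap(frames, function(m, i) {
    i <- as.integer(i)
    tibble(frame = i, time_ns = times[i], res_id = m$res_id,
           res_name = m$res_name, x = m$x, y = m$y, z = m$z)
  })
  new_trajectory(dplyr::bind_rows(rows), temperature = temperature)
}
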
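#' Trajectory container
#'
#' An ordered set of coordinate frames bound to a topology
#' ([molecular_system()] or plain atom count) with a physical frame
#' interval in nanoseconds.
#'
#' @param frames list of `n x 3` matrices, or a `frames x 3n` matrix whose
#'   rows are flattened (x1 y1 z1 x2 ...) coordinates.
#' @param topology optional [molecular_system()].
#' @param frame_interval time between stored frames (ns), > 0.
#' @return Object of class `trajectory` with elements `coords`
#'   (`frames x 3n` matrix), `n_atoms`, `topology`, `frame_interval`.
#' @export
trajectory <- function(frames, topology = NULL, frame_interval = 1) {
  stopifnot(frame_interval > 0)
  if (is.list(frames)) {
    n_at <- unique(vapply(frames, nrow, 1L))
    if (length(n_at) != 1) stop("all frames must have the same atom count")
    coords <- t(vapply(frames, function(f) as.numeric(t(f)),
                       numeric(3 * n_at)))
  } else {
    coords <- as.matrix(frames)
    if (ncol(coords) %% 3 != 0) stop("flat frames must have 3N columns")
    n_at <- ncol(coords) / 3
  }
  if (!is.null(topology) && nrow(topology$coords) != n_at)
    stop("topology atom count does not match frames")
  structure(list(coords = coords, n_atoms = as.integer(n_at),
                 topology = topology, frame_interval = frame_interval),
            class = "trajectory")
}

#' Extract one frame of a trajectory as an n x 3 matrix
#' @param traj a [trajectory()].
#' @param i frame index.
#' @return `n_atoms x 3` coordinate matrix.
#' @export
get_frame <- function(traj, i) {
  matrix(traj$coords[i, ], ncol = 3, byrow = TRUE)
}

n_frames <- function(traj) nrow(traj$coords)

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame with ATOM records carrying element,
#' residue and chain information from the topology when present.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  n <- traj$n_atoms
  top <- traj$topology
  resid <- if (!is.null(top)) top$residue else rep(1L, n)
  chain <- if (!is.null(top)) substr(top$chain, 1, 1) else rep("A", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- get_frame(traj, f)
    writeLines(sprintf("MODEL %8d", f), con)
    lines <- sprintf(
      "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), chain, resid, xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Minimal reader for the files written by [write_trajectory_pdb()] and
#' other fixed-column multi-model PDBs: ATOM/HETATM coordinates are taken
#' from columns 31-54, one frame per MODEL block (a file without MODEL
#' records is a single frame).
#'
#' @param path PDB file path.
#' @param frame_interval frame spacing (ns) for the returned trajectory.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, frame_interval = 1) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) model_starts <- 0L
  frames <- list()
  bounds <- c(model_starts, length(lines) + 1L)
  for (k in seq_along(model_starts)) {
    idx <- which(is_atom & seq_along(lines) > bounds[k] &
                   seq_along(lines) < bounds[k + 1])
    if (length(idx) == 0) next
    at <- lines[idx]
    frames[[length(frames) + 1L]] <- cbind(
      as.numeric(substr(at, 31, 38)),
      as.numeric(substr(at, 39, 46)),
      as.numeric(substr(at, 47, 54)))
  }
  if (length(frames) == 0) stop("no coordinates found in ", path)
  trajectory(frames, frame_interval = frame_interval)
}

#' Write a trajectory as flat per-frame numeric text
#'
#' One row per frame, `3N` whitespace-separated columns
#' (x1 y1 z1 x2 ...), coordinates in Angstrom.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @export
write_trajectory_flat <- function(traj, path) {
  utils::write.table(traj$coords, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a flat-text trajectory
#' @param path file written by [write_trajectory_flat()].
#' @param frame_interval frame spacing (ns).
#' @return A [trajectory()].
#' @export
read_trajectory_flat <- function(path, frame_interval = 1) {
  trajectory(as.matrix(utils::read.table(path)),
             frame_interval = frame_interval)
}

#' Serialize a molecular system to a JSON sidecar plus PDB coordinates
#'
#' @param system a [molecular_system()].
#' @param json_path path for the JSON parameter sidecar.
#' @param pdb_path optional path for a single-model PDB of the coordinates.
#' @export
write_system_json <- function(system, json_path, pdb_path = NULL) {
  obj <- unclass(system)
  obj$coords <- unname(as.data.frame(obj$coords))
  jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(pdb_path)) {
    write_trajectory_pdb(trajectory(list(system$coords), topology = system),
                         pdb_path)
  }
  invisible(json_path)
}

#' Read a molecular system from its JSON sidecar
#' @param json_path file written by [write_system_json()].
#' @return A [molecular_system()].
#' @export
read_system_json <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  molecular_system(as.matrix(obj$coords), obj$charges, obj$sigma,
                   obj$epsilon, obj$radii, obj$masses, obj$residue,
                   obj$chain, obj$group)
}
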
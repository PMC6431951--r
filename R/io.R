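#' Write and read trajectories in XYZ format
#'
#' Plain multi-frame XYZ: per frame a bead count line, a comment line
#' (`frame <i>`), then `C x y z` records in bead order, coordinates in
#' sigma units. Frames are indexed from 0 in the comment line.
#'
#' @param traj a `polyknot_trajectory`, or a list of position matrices,
#'   or a single `polyknot_conformation`.
#' @param path output file.
#' @return `write_xyz` returns `path` invisibly.
#' @export
write_xyz <- function(traj, path) {
  frames <- as_frame_list(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    pos <- frames[[i]]
    writeLines(c(as.character(nrow(pos)), paste("frame", i - 1)), con)
    writeLines(sprintf("C %.9g %.9g %.9g", pos[, 1], pos[, 2], pos[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz` returns a list of N x 3 position matrices.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop("malformed XYZ at line ", i, " (after ", length(frames),
           " complete frames)")
    if (i + 1L + n > length(lines))
      stop("truncated XYZ file: frame ", length(frames),
           " is the last complete frame")
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    if (ncol(parts) < 4)
      stop("malformed XYZ frame ", length(frames))
    pos <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    frames[[length(frames) + 1L]] <- pos
    i <- i + 2L + n
  }
  frames
}

#' Write and read trajectories as LAMMPS dump files
#'
#' The `id type x y z` dialect of the LAMMPS dump format. Atom lines may
#' appear in any order in the input; beads are re-sorted by id on read.
#'
#' @inheritParams write_xyz
#' @param box half-open box bounds written in the header (3 x 2 matrix);
#'   defaults to the coordinate range.
#' @return `write_lammps_dump` returns `path` invisibly.
#' @export
write_lammps_dump <- function(traj, path, box = NULL) {
  frames <- as_frame_list(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    pos <- frames[[i]]
    if (is.null(box)) {
      b <- rbind(range(pos[, 1]), range(pos[, 2]), range(pos[, 3]))
    } else b <- box
    writeLines(c("ITEM: TIMESTEP", as.character(i - 1),
                 "ITEM: NUMBER OF ATOMS", as.character(nrow(pos)),
                 "ITEM: BOX BOUNDS ff ff ff",
                 sprintf("%.9g %.9g", b[, 1], b[, 2]),
                 "ITEM: ATOMS id type x y z",
                 sprintf("%d 1 %.9g %.9g %.9g", seq_len(nrow(pos)),
                         pos[, 1], pos[, 2], pos[, 3])), con)
  }
  invisible(path)
}

#' @rdname write_lammps_dump
#' @return `read_lammps_dump` returns a list of N x 3 position matrices.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  n_done <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("malformed dump at line ", i, " (after ", n_done, " frames)")
    na_line <- which(startsWith(lines[i:length(lines)], "ITEM: NUMBER"))[1]
    n <- as.integer(lines[i + na_line])
    atoms_at <- i + which(startsWith(lines[i:length(lines)],
                                     "ITEM: ATOMS"))[1] - 1L
    if (is.na(atoms_at) || atoms_at + n > length(lines))
      stop("truncated dump file: frame ", n_done, " is the last complete ",
           "frame")
    hdr <- strsplit(lines[atoms_at], "\\s+")[[1]][-(1:2)]
    block <- lines[(atoms_at + 1L):(atoms_at + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    cols <- match(c("id", "x", "y", "z"), hdr)
    if (anyNA(cols)) stop("dump file lacks id/x/y/z columns")
    ids <- as.integer(parts[, cols[1]])
    pos <- matrix(as.numeric(parts[, cols[2:4]]), ncol = 3)
    frames[[length(frames) + 1L]] <- pos[order(ids), , drop = FALSE]
    n_done <- n_done + 1L
    i <- atoms_at + n + 1L
  }
  frames
}

as_frame_list <- function(traj) {
  if (inherits(traj, "polyknot_trajectory"))
    return(lapply(seq_len(n_frames(traj)), function(i) traj$frames[i, , ]))
  if (inherits(traj, "polyknot_conformation")) return(list(traj$positions))
  if (is.matrix(traj)) return(list(traj))
  traj
}

#' Read a trajectory file
#'
#' @param path input file.
#' @param dialect `"xyz"` or `"lammps_dump"`.
#' @return list of N x 3 position matrices (frames indexed from 0 in the
#'   source files; returned 1-based as R lists).
#' @export
read_trajectory <- function(path, dialect = c("xyz", "lammps_dump")) {
  dialect <- match.arg(dialect)
  switch(dialect, xyz = read_xyz(path), lammps_dump = read_lammps_dump(path))
}

#' Write an analysis table with a provenance header
#'
#' Tab-separated table preceded by `#`-comment lines recording the
#' package version, the seed and a hash of the configuration, so every
#' output can be traced to its inputs.
#'
#' @param df data.frame.
#' @param path output file.
#' @param seed seed to record.
#' @param config_hash configuration digest to record (any string).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, seed = NA, config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# polyknot ", as.character(packageVersion("polyknot"))),
    paste0("# seed=", seed, " config_hash=", config_hash)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"))
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}

config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 977)) %%
            4294967291)
}
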
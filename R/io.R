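#' Trajectory output: extended XYZ
#'
#' One frame per call: bead count, a comment line carrying the time and box,
#' then `type x y z` per bead. Frames can be appended to build a trajectory.
#'
#' @param state a [dpd_system()].
#' @param file output path.
#' @param time frame time in tau (written on the comment line).
#' @param append append a frame instead of truncating.
#' @export
write_xyz <- function(state, file, time = state$step * 0.005,
                      append = FALSE) {
  n <- nrow(state$positions)
  L <- state$box$lengths
  con <- base::file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(sprintf("time=%.6g box=%.6g,%.6g,%.6g", time, L[1], L[2], L[3]),
             con)
  writeLines(sprintf("%s %.8g %.8g %.8g", as.character(state$types),
                     state$positions[, 1], state$positions[, 2],
                     state$positions[, 3]), con)
  invisible(file)
}

#' Read an extended XYZ trajectory
#'
#' @param file path written by [write_xyz()].
#' @return List of frames; each frame has `types`, `positions`, `time`,
#'   `box`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    tm <- as.numeric(sub(".*time=([0-9eE+.-]+).*", "\\1", hdr))
    box <- as.numeric(strsplit(sub(".*box=", "", hdr), ",")[[1]])
    block <- lines[i + 1L + seq_len(n)]
    parts <- strsplit(block, " +")
    types <- vapply(parts, `[`, "", 1L)
    pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), n, 3,
                  byrow = TRUE)
    frames[[length(frames) + 1L]] <-
      list(types = types, positions = pos, time = tm, box = box)
    i <- i + 2L + n
  }
  frames
}

#' Trajectory output: LAMMPS dump text dialect
#'
#' Writes `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS pp pp pp / ATOMS id
#' type x y z` blocks compatible with common trajectory readers. Types are
#' written as 1-based integers in the order P, W, H, T.
#'
#' @param state a [dpd_system()].
#' @param file output path.
#' @param append append a frame.
#' @export
write_lammps_dump <- function(state, file, append = FALSE) {
  n <- nrow(state$positions)
  L <- state$box$lengths
  con <- base::file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c("ITEM: TIMESTEP", as.character(as.integer(state$step)),
               "ITEM: NUMBER OF ATOMS", as.character(n),
               "ITEM: BOX BOUNDS pp pp pp",
               sprintf("0 %.8g", L[1]), sprintf("0 %.8g", L[2]),
               sprintf("0 %.8g", L[3]),
               "ITEM: ATOMS id type x y z"), con)
  writeLines(sprintf("%d %d %.8g %.8g %.8g", seq_len(n),
                     match(as.character(state$types), BEAD_TYPES),
                     state$positions[, 1], state$positions[, 2],
                     state$positions[, 3]), con)
  invisible(file)
}

#' Read a LAMMPS dump trajectory
#'
#' @param file path written by [write_lammps_dump()].
#' @return List of frames; each has `step`, `box`, `types` (P/W/H/T),
#'   `positions` (ordered by atom id).
#' @export
read_lammps_dump <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    stopifnot(startsWith(lines[i], "ITEM: TIMESTEP"))
    step <- as.integer(lines[i + 1L])
    n <- as.integer(lines[i + 3L])
    box <- vapply(lines[i + 5:7], function(l)
      as.numeric(strsplit(l, " ")[[1]][2]), numeric(1))
    block <- lines[i + 8L + seq_len(n)]
    m <- matrix(as.numeric(unlist(strsplit(block, " +"))), n, 5, byrow = TRUE)
    ord <- order(m[, 1])
    frames[[length(frames) + 1L]] <-
      list(step = step, box = unname(box),
           types = BEAD_TYPES[m[ord, 2]],
           positions = m[ord, 3:5, drop = FALSE])
    i <- i + 9L + n
  }
  frames
}

#' Checkpoint a simulation state
#'
#' Single-file container with positions, velocities, topology, table, step
#' counter and metadata; restart-exact because the engine's randomness is a
#' pure function of (seed, step, pair).
#'
#' @param state a [dpd_system()].
#' @param file path (`.rds`).
#' @export
save_checkpoint <- function(state, file) {
  saveRDS(state, file)
  invisible(file)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()`: the restored [dpd_system()].
#' @export
load_checkpoint <- function(file) {
  state <- readRDS(file)
  if (!inherits(state, "dpd_system")) stop("not a dpd_system checkpoint")
  state
}

#' Read a scenario configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), mirroring the arguments of
#' [scenario_config()].
#'
#' @param file path.
#' @return A named list.
#' @export
read_config <- function(file) {
  ext <- tolower(tools::file_ext(file))
  cfg <- switch(ext,
    yml = , yaml = yaml::read_yaml(file),
    json = jsonlite::fromJSON(file, simplifyVector = TRUE),
    stop("unsupported config format: .", ext))
  cfg
}

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    yml = , yaml = yaml::write_yaml(config, file),
    json = jsonlite::write_json(config, file, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop("unsupported config format: .", ext))
  invisible(file)
}
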
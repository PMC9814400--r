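# File formats: long-format sensorgram CSV, OpenDX scalar grids,
# multi-frame PDB / XYZ trajectories.

#' Write a plate of sensorgrams to the long-format CSV schema
#'
#' Columns: `plate_id`, `sensor_id`, `well`, `role`, `cycle`,
#' `fragment_id`, `conc_M`, `phase`, `time_s`, `response_nm`,
#' `corrected`. Concentrations are molar, time in seconds, response in
#' nm throughout.
#'
#' @param plate a `bli_plate` (or a list of `sensorgram`s)
#' @param path output file
#' @param plate_id,sensor_id identifiers written to every row
#' @return the path, invisibly
#' @export
write_sensorgrams <- function(plate, path, plate_id = "P1",
                              sensor_id = "S1") {
  if (inherits(plate, "bli_plate")) {
    traces <- plate$traces; lay <- plate$layout
  } else {
    traces <- plate
    lay <- data.frame(cycle = seq_along(traces),
                      role = vapply(traces, function(s) {
                        r <- attr(s, "role"); if (is.null(r)) "sample" else r
                      }, character(1)),
                      fragment_id = vapply(traces, function(s) {
                        f <- attr(s, "fragment_id")
                        if (is.null(f)) NA_character_ else f
                      }, character(1)),
                      conc_M = vapply(traces, function(s)
                        attr(s, "conc_M"), numeric(1)))
  }
  corrected <- isTRUE(attr(plate, "corrected"))
  rows <- lapply(seq_along(traces), function(i) {
    sg <- traces[[i]]
    data.frame(plate_id = plate_id, sensor_id = sensor_id,
               well = sprintf("W%02d", lay$cycle[i]), role = lay$role[i],
               cycle = lay$cycle[i], fragment_id = lay$fragment_id[i],
               conc_M = lay$conc_M[i], phase = sg$phase,
               time_s = sg$time_s, response_nm = sg$response_nm,
               corrected = corrected, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a long-format sensorgram CSV back into a plate
#'
#' @param path CSV written by [write_sensorgrams()]
#' @return a `bli_plate`
#' @export
read_sensorgrams <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  traces <- list(); lay_rows <- list()
  for (cyc in unique(d$cycle)) {
    sub <- d[d$cycle == cyc, , drop = FALSE]
    sg <- data.frame(time_s = sub$time_s, response_nm = sub$response_nm,
                     phase = sub$phase, stringsAsFactors = FALSE)
    attr(sg, "conc_M") <- sub$conc_M[1]
    attr(sg, "role") <- sub$role[1]
    attr(sg, "fragment_id") <- sub$fragment_id[1]
    attr(sg, "cycle") <- cyc
    class(sg) <- c("sensorgram", "data.frame")
    traces[[length(traces) + 1]] <- sg
    lay_rows[[length(lay_rows) + 1]] <-
      data.frame(cycle = cyc, role = sub$role[1],
                 fragment_id = sub$fragment_id[1], conc_M = sub$conc_M[1],
                 stringsAsFactors = FALSE)
  }
  out <- structure(list(traces = traces,
                        layout = do.call(rbind, lay_rows)),
                   class = "bli_plate")
  attr(out, "corrected") <- isTRUE(d$corrected[1])
  out
}

#' Write an occupancy grid as an OpenDX scalar field
#'
#' Text OpenDX format (gridpositions / gridconnections / array), data
#' ordered with the z index varying fastest, three values per line,
#' `%.6e` formatting. Reading a file written by this function and
#' writing it again reproduces the bytes exactly.
#'
#' @param grid an `occupancy_grid`
#' @param path output file
#' @return the path, invisibly
#' @export
write_dx <- function(grid, path) {
  d <- grid$dim; o <- grid$origin; s <- grid$spacing
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", o[1], o[2], o[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", s),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", s),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", s),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  fmt <- sprintf("%.6e", vals)
  idx <- seq_along(fmt)
  lines <- tapply(fmt, (idx - 1) %/% 3, paste, collapse = " ")
  writeLines(as.character(lines), con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"occupancy\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#'
#' @param path OpenDX text file
#' @return an `occupancy_grid`
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("class gridpositions", lines, value = TRUE)[1]
  d <- as.integer(utils::tail(strsplit(gp, "\\s+")[[1]], 3))
  og <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(og, "\\s+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][2:4]), numeric(3)))
  spacing <- dmat[1, 1]
  start <- grep("data follows", lines)[1] + 1
  endattr <- grep("^attribute", lines)[1]
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[start:(endattr - 1)]), "\\s+")))
  stopifnot(length(vals) == prod(d))
  values <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  structure(list(origin = origin, spacing = spacing, dim = d,
                 values = values, n_frames = NA_integer_,
                 n_replicas = 1L),
            class = "occupancy_grid")
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj array `(n_atoms, 3, n_frames)`
#' @param path output file
#' @param element element symbol written for every atom
#' @return the path, invisibly
#' @export
write_traj_xyz <- function(traj, path, element = "C") {
  n_at <- dim(traj)[1]; n_fr <- dim(traj)[3]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_fr)) {
    writeLines(c(as.character(n_at), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", element,
                       traj[, 1, f], traj[, 2, f], traj[, 3, f]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file
#' @return array `(n_atoms, 3, n_frames)`
#' @export
read_traj_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1
  while (i <= length(lines)) {
    n_at <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n_at)]
    m <- t(vapply(strsplit(trimws(block), "\\s+"), function(p)
      as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + n_at
  }
  traj <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) traj[, , f] <- frames[[f]]
  traj
}

#' Write a trajectory as a multi-model PDB
#'
#' Minimal MODEL/ATOM/ENDMDL records (one pseudo-atom residue per atom),
#' readable by standard tools; coordinates are written at PDB precision
#' (0.001 A).
#'
#' @param traj array `(n_atoms, 3, n_frames)`
#' @param path output file
#' @return the path, invisibly
#' @export
write_traj_pdb <- function(traj, path) {
  n_at <- dim(traj)[1]; n_fr <- dim(traj)[3]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_fr)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  C   PRB A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n_at), seq_len(n_at),
      traj[, 1, f], traj[, 2, f], traj[, 3, f]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Uses [bio3d::read.pdb()] with `multi = TRUE`.
#'
#' @param path PDB file
#' @return array `(n_atoms, 3, n_frames)`
#' @export
read_traj_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz  # n_frames x 3*n_atoms
  n_fr <- nrow(xyz); n_at <- ncol(xyz) / 3
  traj <- array(NA_real_, dim = c(n_at, 3, n_fr))
  for (f in seq_len(n_fr))
    traj[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  traj
}
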
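#' Accumulate a voxel occupancy grid from a trajectory
#'
#' Voxel value = fraction of frames in which at least one selected atom
#' falls inside the voxel (binary per frame: several atoms in the same
#' voxel in one frame count once). Voxel membership uses half-open
#' intervals with floor binning, `floor((coord - origin) / spacing)`.
#' By default the origin is snapped to the integer Angstrom floor of the
#' bounding box minus 2 A padding, which makes maps bit-reproducible.
#' Frames are assumed pre-aligned (e.g. on C-alpha atoms).
#'
#' @param traj array `(n_atoms, 3, n_frames)` of coordinates, Angstrom
#' @param atoms indices of the atoms to bin (default: all)
#' @param spacing voxel edge, Angstrom (default 1.0)
#' @param origin grid origin; `NULL` snaps automatically
#' @param dim integer voxel counts per axis; `NULL` covers all input
#' @param count_atoms if `TRUE`, accumulate atom counts per voxel
#'   (density) instead of binary per-frame occupancy
#' @return object of class `occupancy_grid`: list with `origin`,
#'   `spacing`, `dim`, `values` (3D array), `n_frames`, `n_replicas`
#' @export
accumulate_grid <- function(traj, atoms = NULL, spacing = 1,
                            origin = NULL, dim = NULL,
                            count_atoms = FALSE) {
  stopifnot(length(base::dim(traj)) == 3, base::dim(traj)[2] == 3)
  n_frames <- base::dim(traj)[3]
  if (is.null(atoms)) atoms <- seq_len(base::dim(traj)[1])
  xyz <- traj[atoms, , , drop = FALSE]
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  if (is.null(origin)) origin <- floor(lo) - 2
  if (is.null(dim)) dim <- as.integer(ceiling((hi + 2 - origin) / spacing))
  dim <- pmax(dim, 1L)
  if (any(lo < origin) || any(hi >= origin + dim * spacing))
    stop("coordinates fall outside the grid; enlarge origin/dim")

  counts <- array(0, dim = dim)
  nx <- dim[1]; ny <- dim[2]
  for (f in seq_len(n_frames)) {
    idx <- floor(sweep(matrix(xyz[, , f], ncol = 3), 2, origin) / spacing)
    lin <- idx[, 1] + idx[, 2] * nx + idx[, 3] * nx * ny + 1
    if (!count_atoms) lin <- unique(lin)
    tb <- tabulate(lin, nbins = prod(dim))
    counts <- counts + array(tb, dim = dim)
  }
  structure(list(origin = origin, spacing = spacing, dim = dim,
                 values = counts / n_frames, n_frames = n_frames,
                 n_replicas = 1L),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf(paste0("Occupancy grid %d x %d x %d, spacing %.2f A,",
                     " origin (%.1f, %.1f, %.1f)\n"),
              x$dim[1], x$dim[2], x$dim[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  %d frame(s), %d replica(s), max value %.4g\n",
              x$n_frames, x$n_replicas, max(x$values)))
  invisible(x)
}

#' Sum occupancy grids across replicas
#'
#' Voxel-wise sum of per-replica occupancy maps ("sum density map").
#' All grids must share origin, spacing and dimensions.
#'
#' @param grids list of `occupancy_grid`s
#' @return an `occupancy_grid` whose values are the voxel-wise sum and
#'   whose `n_replicas` is the total replica count
#' @export
sum_grids <- function(grids) {
  stopifnot(length(grids) >= 1)
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g$origin, g1$origin)) ||
        g$spacing != g1$spacing || !all(g$dim == g1$dim))
      stop("grid geometries do not match")
  }
  g1$values <- Reduce(`+`, lapply(grids, `[[`, "values"))
  g1$n_replicas <- sum(vapply(grids, `[[`, integer(1), "n_replicas"))
  g1
}

voxel_centers <- function(grid, lin_idx) {
  nx <- grid$dim[1]; ny <- grid$dim[2]
  i0 <- lin_idx - 1
  ix <- i0 %% nx
  iy <- (i0 %/% nx) %% ny
  iz <- i0 %/% (nx * ny)
  cbind(grid$origin[1] + (ix + 0.5) * grid$spacing,
        grid$origin[2] + (iy + 0.5) * grid$spacing,
        grid$origin[3] + (iz + 0.5) * grid$spacing)
}

#' Highest-occupancy sites of a grid
#'
#' Greedy selection of the `k` highest-valued voxels whose centers are
#' pairwise at least `min_separation` apart. Ties are broken
#' deterministically by lexicographic (linear) voxel index.
#'
#' @param grid an `occupancy_grid`
#' @param k number of sites (>= 1)
#' @param min_separation minimum pairwise center distance, Angstrom
#' @return data frame with `site`, `x`, `y`, `z`, `occupancy`
#' @export
top_sites <- function(grid, k = 2, min_separation = 6) {
  stopifnot(k >= 1)
  v <- as.vector(grid$values)
  if (!length(v)) stop("empty grid")
  ord <- order(-v, seq_along(v))  # value desc, then lexicographic index
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) == k) break
    ctr <- voxel_centers(grid, i)
    if (length(sel)) {
      prev <- voxel_centers(grid, sel)
      if (min(sqrt(rowSums(sweep(prev, 2, as.numeric(ctr))^2))) <
          min_separation) next
    }
    sel <- c(sel, i)
  }
  ctrs <- voxel_centers(grid, sel)
  data.frame(site = seq_along(sel), x = ctrs[, 1], y = ctrs[, 2],
             z = ctrs[, 3], occupancy = v[sel])
}

#' Residues within a cutoff of a site center
#'
#' Returns the residues with at least one atom strictly closer than
#' `cutoff` to the center (default 6 A, matching the "< 6 A from the
#' dummy atom" convention; an atom at exactly the cutoff is excluded).
#'
#' @param center length-3 point, Angstrom
#' @param structure data frame with columns `x`, `y`, `z`, `resno`
#'   (optionally `resid`, `chain`); see [as_structure()]
#' @param cutoff distance cutoff, Angstrom
#' @return data frame with one row per included residue (`resno`,
#'   `min_dist`, and `resid`/`chain` when present)
#' @export
site_residues <- function(center, structure, cutoff = 6) {
  if (!nrow(structure)) stop("empty structure")
  d <- sqrt((structure$x - center[1])^2 + (structure$y - center[2])^2 +
            (structure$z - center[3])^2)
  keep <- structure[d < cutoff, , drop = FALSE]
  keep$dist <- d[d < cutoff]
  if (!nrow(keep))
    return(data.frame(resno = integer(0), min_dist = numeric(0)))
  out <- do.call(rbind, lapply(split(keep, keep$resno), function(g) {
    row <- data.frame(resno = g$resno[1], min_dist = min(g$dist))
    if (!is.null(g$resid)) row$resid <- g$resid[1]
    if (!is.null(g$chain)) row$chain <- g$chain[1]
    row
  }))
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a bio3d PDB object to a flat atom table
#'
#' @param pdb a `pdb` object from [bio3d::read.pdb()]
#' @return data frame with `x`, `y`, `z`, `resno`, `resid`, `chain`,
#'   `elety`
#' @export
as_structure <- function(pdb) {
  stopifnot(inherits(pdb, "pdb"))
  a <- pdb$atom
  data.frame(x = a$x, y = a$y, z = a$z, resno = a$resno,
             resid = a$resid, chain = a$chain, elety = a$elety,
             stringsAsFactors = FALSE)
}

#' Detect the start of a binding event in a trajectory
#'
#' The binding event starts at the first frame of the earliest run of at
#' least `n_consec` consecutive frames in which the probe atom is closer
#' than `cutoff` to the site center. Raising `n_consec` can only move
#' the detected start later (or lose the event), never lengthen the
#' interval.
#'
#' @param traj array `(n_atoms, 3, n_frames)`
#' @param center site center, Angstrom
#' @param atom probe atom index
#' @param cutoff distance cutoff, Angstrom
#' @param n_consec minimum run length, frames
#' @return list with `start` and `end` frame indices (end = last frame),
#'   or `NULL` when no qualifying run exists
#' @export
detect_binding_event <- function(traj, center, atom = 1, cutoff = 6,
                                 n_consec = 10) {
  d <- sqrt(colSums((matrix(traj[atom, , ], nrow = 3) - center)^2))
  r <- rle(d < cutoff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= n_consec)
  if (!length(ok)) return(NULL)
  list(start = starts[ok[1]], end = base::dim(traj)[3])
}

grid_values_at <- function(grid, points) {
  idx <- floor(sweep(points, 2, grid$origin) / grid$spacing)
  inside <- idx[, 1] >= 0 & idx[, 1] < grid$dim[1] &
            idx[, 2] >= 0 & idx[, 2] < grid$dim[2] &
            idx[, 3] >= 0 & idx[, 3] < grid$dim[3]
  out <- numeric(nrow(points))
  lin <- idx[inside, 1] + idx[inside, 2] * grid$dim[1] +
         idx[inside, 3] * grid$dim[1] * grid$dim[2] + 1
  out[inside] <- as.vector(grid$values)[lin]
  out
}

#' Representative binding pose across replicas
#'
#' Per replica, the mean coordinates over the binding interval are
#' computed and the frame minimizing the (non-resuperposed) RMSD of the
#' selected atoms to that mean is taken as the replica's pose. Across
#' replicas, each pose is scored by the sum of occupancy-grid values at
#' its atom positions; the highest-scoring pose wins, ties broken by
#' lower replica index.
#'
#' @param replicas list of trajectory arrays `(n_atoms, 3, n_frames)`
#' @param intervals list of binding intervals (as returned by
#'   [detect_binding_event()]); replicas with `NULL` interval are skipped
#' @param grid occupancy grid (typically the replica sum) used for the
#'   agreement score
#' @param atoms atom indices entering the RMSD and the agreement score
#' @return list with `replica`, `frame`, `rmsd`, `agreement`, `pose`
#'   (atom coordinate matrix), or `NULL` if no replica has an interval
#' @export
representative_pose <- function(replicas, intervals, grid, atoms = NULL) {
  best <- NULL
  for (r in seq_along(replicas)) {
    iv <- intervals[[r]]
    if (is.null(iv)) next
    traj <- replicas[[r]]
    if (is.null(atoms)) atoms <- seq_len(base::dim(traj)[1])
    frames <- iv$start:iv$end
    sub <- traj[atoms, , frames, drop = FALSE]
    avg <- apply(sub, c(1, 2), mean)
    rmsd <- vapply(seq_along(frames), function(f)
      sqrt(mean((sub[, , f] - avg)^2) * 3), numeric(1))
    fbest <- frames[which.min(rmsd)]
    pose <- matrix(traj[atoms, , fbest], ncol = 3)
    score <- sum(grid_values_at(grid, pose))
    if (is.null(best) || score > best$agreement)
      best <- list(replica = r, frame = fbest,
                   rmsd = min(rmsd), agreement = score, pose = pose)
  }
  best
}
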
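# Regular lattice shared by all aligned molecules.

#' Construct a grid specification
#'
#' @param origin coordinates (Angstrom) of the first lattice point.
#' @param spacing lattice spacing in Angstrom (default 2.0).
#' @param counts integer vector of lattice points along x, y, z.
#' @return `qsar_grid` object.
#' @export
grid_spec <- function(origin, spacing = 2.0, counts) {
  stopifnot(length(origin) == 3L, length(counts) == 3L, spacing > 0,
            all(counts >= 1L))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 counts = as.integer(counts)),
            class = "qsar_grid")
}

#' @export
print.qsar_grid <- function(x, ...) {
  cat(sprintf("<grid %dx%dx%d, spacing %.2f A, origin (%.2f, %.2f, %.2f)>\n",
              x$counts[1], x$counts[2], x$counts[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of lattice points
#' @param grid a `qsar_grid`.
#' @return integer.
#' @export
n_points <- function(grid) as.integer(prod(grid$counts))

#' Lattice point coordinates
#'
#' Iteration order is x fastest, then y, then z; this order is the column
#' order of descriptor blocks and the voxel order of OpenDX exports.
#'
#' @param grid a `qsar_grid`.
#' @return n_points x 3 matrix of coordinates in Angstrom.
#' @export
grid_points <- function(grid) {
  gx <- grid$origin[1] + grid$spacing * (seq_len(grid$counts[1]) - 1L)
  gy <- grid$origin[2] + grid$spacing * (seq_len(grid$counts[2]) - 1L)
  gz <- grid$origin[3] + grid$spacing * (seq_len(grid$counts[3]) - 1L)
  cbind(x = rep(gx, times = grid$counts[2] * grid$counts[3]),
        y = rep(rep(gy, each = grid$counts[1]), times = grid$counts[3]),
        z = rep(gz, each = grid$counts[1] * grid$counts[2]))
}

#' Build a lattice enclosing an aligned molecule set
#'
#' The box is the union bounding box of all atoms plus `padding` on every
#' side, snapped outward to whole lattice steps so the result is
#' deterministic for a fixed input.
#'
#' @param set a `qsar_molecule_set` (aligned).
#' @param spacing lattice spacing in Angstrom (default 2.0).
#' @param padding clearance added on each side (default 4.0).
#' @return a `qsar_grid`.
#' @export
make_grid <- function(set, spacing = 2.0, padding = 4.0) {
  if (inherits(set, "qsar_molecule")) set <- molecule_set(list(set))
  if (length(set) == 0L) stop("cannot build a grid for an empty set")
  xyz <- do.call(rbind, lapply(set, coords))
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  counts <- pmax(1L, as.integer(ceiling(round((hi - lo) / spacing, 9))) + 1L)
  # center the lattice on the box so padding is symmetric
  origin <- (lo + hi) / 2 - (counts - 1L) * spacing / 2
  grid_spec(origin = origin, spacing = spacing, counts = counts)
}
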
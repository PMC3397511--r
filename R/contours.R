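# StDev*Coeff contour extraction (favored/disfavored voxel sets) and OpenDX
# scalar-field export.

# field kind -> conventional favored/disfavored display colors
CONTOUR_COLORS <- list(
  S = c(favored = "green", disfavored = "yellow"),
  E = c(favored = "blue", disfavored = "red"),
  H = c(favored = "orange", disfavored = "white"),
  D = c(favored = "cyan", disfavored = "purple"),
  A = c(favored = "magenta", disfavored = "red")
)

#' Extract favored/disfavored contour voxels from a StDev*Coeff grid
#'
#' In percentile mode (default), voxels with values strictly above the
#' `fav_pct` percentile of the voxel-value distribution form the favored
#' set, and voxels strictly below the `disfav_pct` percentile the
#' disfavored set. In absolute mode the two levels are taken as given. A
#' constant grid yields an empty contour set with a warning. `NA` voxels
#' (columns dropped by the minimum-sigma filter) never contour.
#'
#' @param values numeric vector over lattice points (one field's
#'   StDev*Coeff values, see [stdev_coeff_grid()]).
#' @param grid the `qsar_grid` the values live on.
#' @param fav_pct,disfav_pct percentile thresholds in (0, 100).
#' @param mode `"percentile"` or `"absolute"`.
#' @param levels for absolute mode: `c(disfavored_level, favored_level)`.
#' @param field field kind label (sets the conventional colors).
#' @return `qsar_contours`: list with `favored`/`disfavored` data.frames
#'   (point, x, y, z, value), `thresholds`, `field`, `colors`.
#' @export
extract_contours <- function(values, grid, fav_pct = 80, disfav_pct = 20,
                             mode = c("percentile", "absolute"),
                             levels = NULL, field = "S") {
  mode <- match.arg(mode)
  stopifnot(length(values) == n_points(grid))
  if (mode == "percentile")
    stopifnot(fav_pct > 0, fav_pct < 100, disfav_pct > 0, disfav_pct < 100)
  ok <- is.finite(values)
  pts <- grid_points(grid)
  empty <- data.frame(point = integer(), x = numeric(), y = numeric(),
                      z = numeric(), value = numeric())
  colors <- CONTOUR_COLORS[[field]] %||%
    c(favored = "green", disfavored = "yellow")
  result <- function(fav_idx, disfav_idx, thr) {
    voxels <- function(idx) if (length(idx) == 0L) empty else
      data.frame(point = idx, x = pts[idx, 1], y = pts[idx, 2],
                 z = pts[idx, 3], value = values[idx])
    structure(list(favored = voxels(fav_idx), disfavored = voxels(disfav_idx),
                   thresholds = thr, field = field, colors = colors),
              class = "qsar_contours")
  }
  if (!any(ok)) return(result(integer(), integer(), c(NA_real_, NA_real_)))
  v <- values[ok]
  if (max(v) == min(v)) {
    warning("constant grid: no contours extracted")
    return(result(integer(), integer(), c(NA_real_, NA_real_)))
  }
  if (mode == "percentile") {
    thr <- quantile(v, c(disfav_pct, fav_pct) / 100, names = FALSE)
  } else {
    stopifnot(length(levels) == 2L)
    thr <- sort(as.numeric(levels))
  }
  fav <- which(ok & values > thr[2])
  disfav <- which(ok & values < thr[1])
  result(fav, disfav, thr)
}

#' @export
print.qsar_contours <- function(x, ...) {
  cat(sprintf("<contours [%s]: %d favored (%s), %d disfavored (%s)>\n",
              x$field, nrow(x$favored), x$colors[["favored"]],
              nrow(x$disfavored), x$colors[["disfavored"]]))
  invisible(x)
}

#' Export a lattice scalar field as OpenDX
#'
#' Writes the standard OpenDX regular-grid format readable by PyMOL, VMD and
#' ChimeraX. Voxel order follows the package grid convention (x fastest) and
#' is re-ordered into the DX convention (z fastest) on write; `NA` values
#' are written as 0 with the fill recorded in a comment.
#'
#' @param values numeric vector over lattice points.
#' @param grid the `qsar_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_dx <- function(values, grid, path) {
  stopifnot(length(values) == n_points(grid))
  nx <- grid$counts[1]; ny <- grid$counts[2]; nz <- grid$counts[3]
  # package order: x fastest; DX order: z fastest
  arr <- array(values, dim = c(nx, ny, nz))
  dxvals <- as.vector(aperm(arr, c(3, 2, 1)))
  nafill <- anyNA(dxvals)
  dxvals[is.na(dxvals)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by qsar3d",
    if (nafill) "# NA voxels (filtered columns) written as 0",
    sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(dxvals))), con)
  writeLines(vapply(split(dxvals, ceiling(seq_along(dxvals) / 3)),
                    function(v) paste(sprintf("%.6e", v), collapse = " "),
                    character(1)), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [export_dx()]
#'
#' @param path DX file.
#' @return list with `values` (package voxel order, x fastest) and `grid`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  counts_line <- grep("gridpositions counts", lines, value = TRUE)[1]
  counts <- as.integer(strsplit(sub(".*counts ", "", counts_line), " ")[[1]])
  origin <- as.numeric(strsplit(sub("^origin ", "",
                                    grep("^origin", lines, value = TRUE)[1]),
                                " ")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  spacing <- as.numeric(strsplit(sub("^delta ", "", deltas[1]), " ")[[1]])[1]
  start <- grep("data follows", lines)[1]
  end <- grep("^attribute", lines)[1]
  nums <- as.numeric(unlist(strsplit(trimws(lines[(start + 1):(end - 1)]),
                                     "\\s+")))
  arr <- array(nums, dim = rev(counts))
  values <- as.vector(aperm(arr, c(3, 2, 1)))
  list(values = values,
       grid = grid_spec(origin = origin, spacing = spacing, counts = counts))
}

#' Write a PyMOL loading script for a set of contour DX files
#'
#' Convenience companion to [export_dx()]: emits `load`/`isosurface`
#' commands with the conventional colors so the favored/disfavored surfaces
#' can be inspected next to the aligned molecules.
#'
#' @param entries data.frame with columns `path`, `level`, `color`, `name`.
#' @param path output `.pml` file.
#' @return `path`, invisibly.
#' @export
write_pymol_script <- function(entries, path) {
  lines <- unlist(lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    obj <- tools::file_path_sans_ext(basename(e$path))
    c(sprintf("load %s, %s", e$path, obj),
      sprintf("isosurface %s_surf, %s, %.4f", e$name, obj, e$level),
      sprintf("color %s, %s_surf", e$color, e$name))
  }))
  writeLines(lines, path)
  invisible(path)
}
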
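#' Voxel lattice geometry
#'
#' A `grid3d` describes an axis-aligned voxel lattice in a single world frame
#' of reference: integer dimensions, per-axis spacing in millimetres, and the
#' world coordinate (mm) of the *center* of the first voxel (index `(1,1,1)`).
#' Every image and mask in the package lives on one.
#'
#' @param dims integer triple `(nx, ny, nz)`, all `>= 1`.
#' @param spacing numeric triple, voxel edge lengths in mm, all `> 0`.
#' @param origin numeric triple, world coordinate (mm) of the center of the
#'   first voxel. Default places the grid's world extent symmetric about 0.
#' @return An object of class `grid3d`.
#' @examples
#' g <- grid3d(c(64, 64, 32), spacing = c(2, 2, 3))
#' voxel_volume(g)   # mm^3
#' @export
grid3d <- function(dims, spacing, origin = NULL) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  stopifnot(length(dims) == 3L, length(spacing) == 3L)
  if (any(dims < 1L)) stop("grid dims must all be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid spacing must be finite and > 0 on every axis")
  }
  if (is.null(origin)) {
    # extent symmetric about the world origin
    origin <- -(dims - 1L) * spacing / 2
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume of a grid in cubic millimetres
#' @param grid a [grid3d()].
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Per-axis voxel-center world coordinates
#' @param grid a [grid3d()].
#' @param axis 1, 2 or 3.
#' @return numeric vector of length `dims[axis]` (mm).
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' World extent of a grid (outer voxel faces)
#' @param grid a [grid3d()].
#' @return 2 x 3 matrix: rows = (low, high), columns = axes (mm).
#' @export
grid_extent <- function(grid) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dims - 1) * grid$spacing + grid$spacing / 2
  rbind(lo = lo, hi = hi)
}

#' Construct a grid with given spacing covering a world extent
#'
#' The number of voxels per axis is the smallest count whose footprint covers
#' the requested extent; the grid is centered on the extent's midpoint.
#'
#' @param extent 2 x 3 matrix as returned by [grid_extent()], or a `grid3d`
#'   whose extent is used.
#' @param spacing numeric triple (mm).
#' @return a [grid3d()].
#' @export
grid_covering <- function(extent, spacing) {
  if (inherits(extent, "grid3d")) extent <- grid_extent(extent)
  spacing <- as.numeric(spacing)
  span <- extent[2, ] - extent[1, ]
  dims <- pmax(1L, as.integer(ceiling(span / spacing - 1e-9)))
  mid <- (extent[1, ] + extent[2, ]) / 2
  origin <- mid - (dims - 1L) * spacing / 2
  grid3d(dims, spacing, origin)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Scalar image on a voxel lattice
#'
#' An `image3d` couples a 3D numeric array with the [grid3d()] it lives on
#' and a unit tag (`"Bq/mL"` for activity-concentration maps, `"SUV"` for
#' calibrated maps, `"label"` for integer label maps, `"mask"` for binaries).
#'
#' @param values numeric 3D array with `dim(values) == grid$dims`.
#' @param grid a [grid3d()].
#' @param unit unit tag string.
#' @return An object of class `image3d`.
#' @export
image3d <- function(values, grid, unit = "Bq/mL") {
  stopifnot(inherits(grid, "grid3d"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$dims)) {
    stop("value array shape does not match grid dims")
  }
  if (any(!is.finite(values))) stop("image values must all be finite")
  structure(list(values = values, grid = grid, unit = unit),
            class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  cat(sprintf("<image3d> [%s] range [%.4g, %.4g]\n", x$unit,
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Total activity in an activity-concentration image
#' @param image an [image3d()] in Bq/mL.
#' @return total activity in MBq.
#' @export
total_activity <- function(image) {
  # Bq/mL * mm^3 -> Bq/1000, then -> MBq
  sum(image$values) * voxel_volume(image$grid) / 1000 / 1e6
}

#' Matrix of all voxel-center world coordinates
#' @param grid a [grid3d()].
#' @return n x 3 matrix in array (column-major) voxel order.
#' @export
voxel_centers <- function(grid) {
  cbind(
    x = rep(axis_coords(grid, 1), times = grid$dims[2] * grid$dims[3]),
    y = rep(rep(axis_coords(grid, 2), each = grid$dims[1]), times = grid$dims[3]),
    z = rep(axis_coords(grid, 3), each = grid$dims[1] * grid$dims[2])
  )
}
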
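#' Volume of a binary mask in mL
#' @param mask logical array (or a [voi()]).
#' @param grid the [grid3d()] the mask lives on (ignored for a `voi`).
#' @return volume in mL (voxel count x voxel volume).
#' @export
volume_of <- function(mask, grid = NULL) {
  if (inherits(mask, "voi")) { grid <- mask$grid; mask <- mask$mask }
  stopifnot(inherits(grid, "grid3d"))
  sum(mask) * voxel_volume(grid) / 1000
}

#' Signed percent deviation of a measured volume from the actual volume
#'
#' `100 * (measured - actual) / actual`; oversegmentation is positive.
#'
#' @param measured measured volume (mL).
#' @param actual actual volume (mL), `> 0`.
#' @return signed percent (numeric, unrounded).
#' @examples
#' percent_deviation(0.4874, 0.3)   # +62.5
#' @export
percent_deviation <- function(measured, actual) {
  if (any(actual <= 0)) stop("actual volume must be > 0")
  100 * (measured - actual) / actual
}

#' Report-style rounding of a percent deviation
#'
#' Integer percent when the magnitude is `>= 1`\%, one decimal below —
#' matching the bracketed deviations of the reference report layout.
#'
#' @param dev signed percent deviation(s).
#' @return character vector like `"+62%"`, `"-0.4%"`.
#' @export
format_deviation <- function(dev) {
  vapply(dev, function(d) {
    if (abs(d) >= 0.95) sprintf("%+d%%", as.integer(round(d)))
    else sprintf("%+.1f%%", round(d, 1))
  }, "")
}

# transfer a mask to a target grid by nearest-neighbor
mask_to_grid <- function(mask, grid, target) {
  img <- image3d(array(as.numeric(mask), dim(mask)), grid, unit = "mask")
  out <- resample_image(img, target, method = "nearest", fill = 0)
  out$values > 0.5
}

#' Shape coefficient (Jaccard index) of two binary volumes
#'
#' `SC = |A intersect B| / |A union B|`, in \[0, 1\]; `SC = 1` iff the masks
#' are identical on the comparison grid. When the masks live on different
#' grids, both are compared on the finer grid of the pair (smaller voxel
#' volume), with nearest-neighbor mask transfer.
#'
#' @param mask_a,mask_b logical arrays or [voi()] objects.
#' @param grid_a,grid_b grids for plain-array masks (same grid assumed when
#'   both omitted and shapes match).
#' @return SC in \[0, 1\]; `NA` (with a warning) when both masks are empty.
#' @export
shape_coefficient <- function(mask_a, mask_b, grid_a = NULL, grid_b = NULL) {
  if (inherits(mask_a, "voi")) { grid_a <- mask_a$grid; mask_a <- mask_a$mask }
  if (inherits(mask_b, "voi")) { grid_b <- mask_b$grid; mask_b <- mask_b$mask }
  if (is.null(grid_a) && is.null(grid_b)) {
    stopifnot(identical(dim(mask_a), dim(mask_b)))
    a <- as.logical(mask_a); b <- as.logical(mask_b)
  } else {
    stopifnot(inherits(grid_a, "grid3d"), inherits(grid_b, "grid3d"))
    if (same_grid(grid_a, grid_b)) {
      a <- as.logical(mask_a); b <- as.logical(mask_b)
    } else if (voxel_volume(grid_a) <= voxel_volume(grid_b)) {
      a <- as.logical(mask_a)
      b <- mask_to_grid(mask_b, grid_b, grid_a)
    } else {
      a <- mask_to_grid(mask_a, grid_a, grid_b)
      b <- as.logical(mask_b)
    }
  }
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both masks empty; shape coefficient undefined")
    return(NA_real_)
  }
  sum(a & b) / uni
}

#' Cumulative shape coefficient
#'
#' The product of per-structure / per-stage shape coefficients: an overall
#' score for one interpolation chain. Never exceeds its smallest factor.
#'
#' @param scores numeric vector of SCs in \[0, 1\].
#' @return scalar product.
#' @export
cumulative_sc <- function(scores) {
  if (length(scores) == 0) stop("empty score list")
  stopifnot(all(scores >= 0 & scores <= 1))
  prod(scores)
}

#' Select the best interpolation chain
#'
#' Default compromise rule: rank chains by cumulative SC; chains whose
#' cumulative SC is within `tol` (relative, default 10%) of the best are
#' near-ties, resolved by the smaller mean absolute percent volume
#' deviation. Remaining ties go to the first chain in input (canonical)
#' order. The rule is a scoring function argument so other compromises can
#' be plugged in.
#'
#' @param scores data.frame with columns `chain` (id), `cum_sc`, and
#'   `mean_abs_dev` (mean |percent deviation| across structures).
#' @param tol relative near-tie tolerance on cumulative SC.
#' @param rule optional function(scores) returning the selected row index.
#' @return the selected chain id (character).
#' @export
select_chain <- function(scores, tol = 0.10, rule = NULL) {
  stopifnot(nrow(scores) >= 1)
  if (!is.null(rule)) return(scores$chain[rule(scores)])
  best <- max(scores$cum_sc)
  near <- which(scores$cum_sc >= best * (1 - tol))
  pick <- near[order(scores$mean_abs_dev[near])][1]
  scores$chain[pick]
}
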
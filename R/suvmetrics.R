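#' Volume of interest
#'
#' A binary mask bound to the grid of the image it will be applied to.
#'
#' @param mask logical 3D array.
#' @param grid the [grid3d()] the mask lives on.
#' @param label structure name.
#' @param provenance one of `"analytic"`, `"segmentation"`, `"manual"`.
#' @return a `voi` object.
#' @export
voi <- function(mask, grid, label = "voi", provenance = "manual") {
  stopifnot(inherits(grid, "grid3d"))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(as.integer(dim(mask)), grid$dims)) {
    stop("mask shape does not match grid dims")
  }
  if (!any(mask)) stop("VOI is empty")
  structure(list(mask = mask, grid = grid, label = label,
                 provenance = provenance), class = "voi")
}

#' Analytic VOI from a phantom primitive
#'
#' Voxel membership by center-in-solid on the given grid — the standard way
#' to delineate a known insert on a reconstructed image.
#'
#' @param prim a primitive (see [prim_sphere()]).
#' @param grid target [grid3d()].
#' @return a [voi()] with provenance `"analytic"`.
#' @export
voi_from_primitive <- function(prim, grid) {
  inside <- prim_contains(prim, voxel_centers(grid))
  voi(array(inside, grid$dims), grid, label = prim$label,
      provenance = "analytic")
}

# offsets (index space) of voxels whose centers fall inside a sphere of
# `diameter` mm centred on a voxel center
sphere_offsets <- function(grid, diameter) {
  r <- diameter / 2
  n <- floor(r / grid$spacing)
  off <- as.matrix(expand.grid(-n[1]:n[1], -n[2]:n[2], -n[3]:n[3]))
  d2 <- (off[, 1] * grid$spacing[1])^2 + (off[, 2] * grid$spacing[2])^2 +
        (off[, 3] * grid$spacing[3])^2
  off[d2 <= r^2, , drop = FALSE]
}

#' SUV statistics over a VOI
#'
#' `suvmax` and `suvmean` are the maximum and mean over the VOI. `suvpeak`
#' is the largest sphere-mean obtainable by centering a `peak_diameter`
#' sphere (12 mm default) on any VOI voxel center; sphere membership is by
#' voxel-center-in-sphere in world mm, so anisotropic grids are handled
#' correctly. The peak sphere may extend beyond the VOI (but not beyond the
#' image). `suvpeak` is `NA` if no candidate sphere contains a voxel.
#'
#' @param image an [image3d()].
#' @param v a [voi()] on the same grid.
#' @param peak_diameter sphere diameter in mm (default 12); `NULL` skips
#'   the peak search (`suvpeak = NA`).
#' @return a `suv_stats` object: `suvmax`, `suvmean`, `suvpeak`,
#'   `volume_ml`, `peak_center` (world mm or `NULL`), `n_voxels`.
#' @export
suv_stats <- function(image, v, peak_diameter = 12) {
  stopifnot(inherits(image, "image3d"), inherits(v, "voi"))
  if (!same_grid(image$grid, v$grid)) {
    stop("image and VOI must share a grid")
  }
  vals <- image$values[v$mask]
  g <- image$grid
  best <- -Inf; best_center <- NULL
  if (!is.null(peak_diameter)) {
    off <- sphere_offsets(g, peak_diameter)
    cand <- which(v$mask, arr.ind = TRUE)
    dm <- dim(image$values)
    interior <- cand[, 1] > -min(off[, 1]) & cand[, 1] <= dm[1] - max(off[, 1]) &
                cand[, 2] > -min(off[, 2]) & cand[, 2] <= dm[2] - max(off[, 2]) &
                cand[, 3] > -min(off[, 3]) & cand[, 3] <= dm[3] - max(off[, 3])
    if (any(interior)) {         # vectorized fast path: no bounds clipping
      lin_c <- cand[interior, 1] + (cand[interior, 2] - 1L) * dm[1] +
               (cand[interior, 3] - 1L) * dm[1] * dm[2]
      lin_o <- off[, 1] + off[, 2] * dm[1] + off[, 3] * dm[1] * dm[2]
      means <- rowMeans(matrix(image$values[outer(lin_c, lin_o, "+")],
                               nrow = length(lin_c)))
      i <- which.max(means)
      best <- means[i]
      best_center <- g$origin + (cand[interior, , drop = FALSE][i, ] - 1) *
                     g$spacing
    }
    for (i in which(!interior)) {    # edge candidates: clip sphere to image
      ijk <- sweep(off, 2, cand[i, ], "+")
      keep <- ijk[, 1] >= 1 & ijk[, 1] <= dm[1] &
              ijk[, 2] >= 1 & ijk[, 2] <= dm[2] &
              ijk[, 3] >= 1 & ijk[, 3] <= dm[3]
      if (!any(keep)) next
      m <- mean(image$values[ijk[keep, , drop = FALSE]])
      if (m > best) {
        best <- m
        best_center <- g$origin + (cand[i, ] - 1) * g$spacing
      }
    }
  }
  structure(list(suvmax = max(vals), suvmean = mean(vals),
                 suvpeak = if (is.finite(best)) best else NA_real_,
                 volume_ml = sum(v$mask) * voxel_volume(g) / 1000,
                 peak_center = best_center,
                 n_voxels = sum(v$mask)),
            class = "suv_stats")
}

#' @export
print.suv_stats <- function(x, ...) {
  cat(sprintf("<suv_stats> max %.4g  mean %.4g  peak %s  volume %.4g mL (%d voxels)\n",
              x$suvmax, x$suvmean,
              if (is.na(x$suvpeak)) "NA" else sprintf("%.4g", x$suvpeak),
              x$volume_ml, x$n_voxels))
  invisible(x)
}

#' EARL recovery-coefficient acceptance limits
#'
#' Presets as printed for the two accreditations: EARL1 accepts RC in
#' 0.27-0.43, EARL2 in 0.39-0.61. Bounds are inclusive at both ends.
#'
#' @param protocol `"EARL1"` or `"EARL2"`, or `"custom"` with explicit
#'   bounds.
#' @param lower,upper custom bounds (required when `protocol = "custom"`).
#' @param metric which RC metric the limits apply to (informational).
#' @return an `rc_limits` object.
#' @export
rc_limits <- function(protocol = c("EARL1", "EARL2", "custom"),
                      lower = NULL, upper = NULL, metric = "mean") {
  protocol <- match.arg(protocol)
  if (protocol == "EARL1") { lower <- 0.27; upper <- 0.43 }
  if (protocol == "EARL2") { lower <- 0.39; upper <- 0.61 }
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  structure(list(protocol = protocol, metric = metric,
                 lower = lower, upper = upper), class = "rc_limits")
}

#' Recovery coefficients of phantom inserts
#'
#' RC is the ratio of the measured to the actual activity concentration of a
#' known insert: `rc_max = measured max / actual`, `rc_mean = measured mean /
#' actual`, `rc_peak = sphere-peak / actual`. The VOI is either the analytic
#' insert geometry evaluated on the image grid (`voi_policy = "analytic"`)
#' or a fractional-max threshold region (`voi_policy = "threshold"`).
#'
#' @param image reconstructed [image3d()] (activity units matching the
#'   ground-truth concentrations, or SUV with SUV-scaled truth).
#' @param truth a `ground_truth` from [rasterize()], geometrically aligned
#'   with `image`.
#' @param voi_policy `"analytic"` or `"threshold"`.
#' @param threshold_fraction fraction of the ROI max for the threshold
#'   policy (default 0.41).
#' @param peak_diameter SUVpeak sphere diameter, mm.
#' @return data.frame with one row per insert: label, actual concentration,
#'   measured values, `rc_max`, `rc_mean`, `rc_peak`, VOI volume.
#' @export
recovery_coefficients <- function(image, truth,
                                  voi_policy = c("analytic", "threshold"),
                                  threshold_fraction = 0.41,
                                  peak_diameter = 12) {
  voi_policy <- match.arg(voi_policy)
  stopifnot(inherits(image, "image3d"), inherits(truth, "ground_truth"))
  ins <- truth$spec$inserts
  rows <- lapply(ins, function(p) {
    actual <- p$conc
    if (actual <= 0) stop(sprintf("insert '%s' has zero actual concentration",
                                  p$label))
    v <- voi_from_primitive(p, image$grid)
    if (voi_policy == "threshold") {
      bb <- prim_bbox(p)
      m <- threshold_matv(image, roi = bb, fraction = threshold_fraction)
      v <- voi(m, image$grid, label = p$label, provenance = "segmentation")
    }
    s <- suv_stats(image, v, peak_diameter = peak_diameter)
    data.frame(label = p$label, actual_conc = actual,
               measured_max = s$suvmax, measured_mean = s$suvmean,
               measured_peak = s$suvpeak,
               rc_max = s$suvmax / actual, rc_mean = s$suvmean / actual,
               rc_peak = s$suvpeak / actual,
               voi_volume_ml = s$volume_ml,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check recovery coefficients against acceptance limits
#'
#' @param records data.frame from [recovery_coefficients()].
#' @param limits an [rc_limits()].
#' @param metric which RC column to check: `"mean"`, `"max"` or `"peak"`.
#' @return the records with `status` (`"in"`, `"below"`, `"above"`) and an
#'   attribute `verdict` (TRUE when every insert is in range, bounds
#'   inclusive).
#' @export
check_limits <- function(records, limits, metric = c("mean", "max", "peak")) {
  stopifnot(inherits(limits, "rc_limits"))
  metric <- match.arg(metric)
  rc <- records[[paste0("rc_", metric)]]
  status <- ifelse(rc < limits$lower, "below",
                   ifelse(rc > limits$upper, "above", "in"))
  records$status <- status
  attr(records, "verdict") <- all(status == "in")
  records
}

#' Uniformity / SUV-calibration check
#'
#' The calibration phantom procedure: the mean SUV over a central VOI of the
#' uniform phantom must be 1 within a tolerance (default +-10%).
#'
#' @param image SUV [image3d()].
#' @param central_voi a [voi()] well inside the phantom.
#' @param tolerance accepted relative error (default 0.10).
#' @return list with `suvmean`, `deviation` and logical `pass`.
#' @export
uniformity_check <- function(image, central_voi, tolerance = 0.10) {
  stopifnot(inherits(image, "image3d"), inherits(central_voi, "voi"))
  if (image$unit != "SUV") stop("uniformity check expects an SUV image")
  m <- mean(image$values[central_voi$mask])
  list(suvmean = m, deviation = m - 1, pass = abs(m - 1) <= tolerance)
}
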
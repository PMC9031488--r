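#' 3D image resampling
#'
#' Resamples an image to a target grid by evaluating an interpolant of the
#' source image at every target voxel center (world mm). Three methods are
#' supported, all separable tensor products of 1D rules:
#'
#' * `"nearest"` — closest source voxel center, exact half-way points broken
#'   toward the lower index (reproducibility);
#' * `"linear"` — trilinear on the 8 enclosing voxel centers;
#' * `"spline"` — interpolating tricubic spline (mirror-padded samples,
#'   natural end conditions on the padding). Exactly interpolating: at
#'   source sample points it reproduces the samples. May overshoot the
#'   source range, unlike the other two.
#'
#' Target centers outside the source voxel footprint take `fill`; centers
#' inside the footprint but beyond the outermost sample center are
#' edge-clamped (nearest/linear) or mirror-extended (spline).
#'
#' @param image an [image3d()].
#' @param target a [grid3d()].
#' @param method `"nearest"`, `"linear"` or `"spline"`.
#' @param fill value for out-of-extent target voxels.
#' @return [image3d()] on `target`.
#' @export
resample_image <- function(image, target,
                           method = c("linear", "nearest", "spline"),
                           fill = 0) {
  method <- match.arg(method)
  stopifnot(inherits(image, "image3d"), inherits(target, "grid3d"))
  if (any(target$dims < 1L)) stop("degenerate target grid")
  g <- image$grid
  A <- vector("list", 3)
  outside <- vector("list", 3)
  for (a in 1:3) {
    src <- axis_coords(g, a)
    tgt <- axis_coords(target, a)
    u <- (tgt - g$origin[a]) / g$spacing[a] + 1       # continuous index
    outside[[a]] <- u < 0.5 - 1e-9 | u > g$dims[a] + 0.5 + 1e-9
    A[[a]] <- interp_matrix_1d(u, g$dims[a], method)
  }
  vals <- image$values
  d <- dim(vals)
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(vals, perm), nrow = d[a])
    out <- A[[a]] %*% m
    d[a] <- nrow(A[[a]])
    vals <- aperm(array(out, c(d[a], dim(vals)[setdiff(1:3, a)])),
                  order(perm))
  }
  bad <- outer(outer(outside[[1]], outside[[2]], "|"), outside[[3]], "|")
  vals[bad] <- fill
  image3d(vals, target, image$unit)
}

# 1D interpolation operator: rows = target positions (continuous source
# index u, 1-based), cols = source samples
interp_matrix_1d <- function(u, ns, method) {
  nt <- length(u)
  if (method == "nearest") {
    j <- ceiling(u - 0.5)                 # ties toward the lower index
    j <- pmin(pmax(j, 1L), ns)
    M <- matrix(0, nt, ns)
    M[cbind(seq_len(nt), j)] <- 1
    return(M)
  }
  if (method == "linear") {
    uc <- pmin(pmax(u, 1), ns)            # edge clamp
    j0 <- pmin(floor(uc), ns - 1); j0[ns == 1] <- 1
    if (ns == 1L) return(matrix(1, nt, 1))
    w <- uc - j0
    M <- matrix(0, nt, ns)
    M[cbind(seq_len(nt), j0)] <- M[cbind(seq_len(nt), j0)] + (1 - w)
    M[cbind(seq_len(nt), j0 + 1)] <- M[cbind(seq_len(nt), j0 + 1)] + w
    return(M)
  }
  # spline: interpolating cubic on mirror-padded samples
  if (ns == 1L) return(matrix(1, nt, 1))
  if (ns < 4L) return(interp_matrix_1d(u, ns, "linear"))  # too few samples
  p <- 3L
  ppos <- seq(1 - p, ns + p)
  fold <- mirror_index(ppos, ns)
  Mp <- matrix(0, nt, length(ppos))
  uc <- pmin(pmax(u, 1 - p), ns + p)
  for (j in seq_along(ppos)) {
    e <- numeric(length(ppos)); e[j] <- 1
    Mp[, j] <- stats::splinefun(ppos, e, method = "natural")(uc)
  }
  M <- matrix(0, nt, ns)
  for (j in seq_along(ppos)) M[, fold[j]] <- M[, fold[j]] + Mp[, j]
  M
}

# reflect indices into [1, ns] (mirror about the edge samples)
mirror_index <- function(i, ns) {
  if (ns == 1L) return(rep(1L, length(i)))
  per <- 2L * (ns - 1L)
  i <- (i - 1L) %% per
  i <- ifelse(i >= ns - 1L, per - i, i)
  as.integer(i + 1L)
}

#' Two-stage resampling chain
#'
#' The planning-pipeline resampling path: PET grid -> CT grid (image
#' fusion), then CT grid -> dose-calculation grid. The stage methods may
#' differ; the study design sweeps all nine combinations. Default grids keep
#' the patient-protocol spacings (CT: 800 mm field of view / 512 = 1.5625 mm;
#' dose: 800 / 256 = 3.125 mm) but cover only the phantom extent.
#'
#' @param stage1,stage2 interpolation methods (see [resample_image()]).
#' @param ct_grid,dose_grid [grid3d()] objects; when `NULL` they are derived
#'   from the image passed to [run_chain()].
#' @return a `resampling_chain` object.
#' @export
resampling_chain <- function(stage1 = "linear", stage2 = "linear",
                             ct_grid = NULL, dose_grid = NULL) {
  methods <- c("nearest", "linear", "spline")
  stopifnot(stage1 %in% methods, stage2 %in% methods)
  structure(list(stage1 = stage1, stage2 = stage2,
                 ct_grid = ct_grid, dose_grid = dose_grid),
            class = "resampling_chain")
}

#' Default CT and dose grids covering an image
#'
#' The CT grid covers the image extent at the CT spacing; the dose grid is
#' derived from the CT grid by halving the resolution *face-aligned* (the
#' dose voxel footprint tiles the CT footprint from the same lower corner,
#' as when a 512-pixel slice becomes a 256-pixel slice over the same field
#' of view). Dose voxel centers therefore fall on CT cell corners, where
#' the interpolation methods genuinely differ.
#'
#' @param image an [image3d()] (or a [grid3d()]).
#' @param ct_spacing CT grid spacing in mm.
#' @param dose_factor linear coarsening factor CT -> dose (default 2).
#' @return list with `ct` and `dose` [grid3d()] objects.
#' @export
default_chain_grids <- function(image,
                                ct_spacing = rep(800 / 512, 3),
                                dose_factor = 2) {
  g <- if (inherits(image, "image3d")) image$grid else image
  ct <- grid_covering(g, ct_spacing)
  dose_spacing <- ct$spacing * dose_factor
  dose_dims <- pmax(1L, as.integer(ceiling(ct$dims / dose_factor)))
  dose_origin <- (ct$origin - ct$spacing / 2) + dose_spacing / 2
  list(ct = ct, dose = grid3d(dose_dims, dose_spacing, dose_origin))
}

#' Run a two-stage resampling chain
#'
#' Stage outputs are retained separately so segmentation and metrics can be
#' computed on both the CT-grid and the dose-grid image.
#'
#' @param image an [image3d()] on the PET (protocol) grid.
#' @param chain a [resampling_chain()].
#' @param fill out-of-extent fill value.
#' @return list with elements `ct` and `dose` ([image3d()]s).
#' @export
run_chain <- function(image, chain, fill = 0) {
  stopifnot(inherits(image, "image3d"), inherits(chain, "resampling_chain"))
  grids <- default_chain_grids(image)
  ct_grid <- if (is.null(chain$ct_grid)) grids$ct else chain$ct_grid
  dose_grid <- if (is.null(chain$dose_grid)) grids$dose else chain$dose_grid
  ct <- resample_image(image, ct_grid, chain$stage1, fill = fill)
  dose <- resample_image(ct, dose_grid, chain$stage2, fill = fill)
  list(ct = ct, dose = dose)
}
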
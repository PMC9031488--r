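#' Segmentation parameters
#'
#' Parameters of the metabolic-target segmentation: the fractional-max
#' threshold defining the metabolic active tumor volume (MATV), and the
#' affinity-propagation (AP) settings used to split heterogeneous uptake
#' into sub-volumes. One threshold is computed per region of interest and
#' reused for all structures within it; AP parameters are set once and kept
#' frozen across grids and protocols.
#'
#' @param fraction MATV threshold as a fraction of the ROI maximum, in
#'   (0, 1); default 0.41.
#' @param damping AP damping factor in \[0.5, 1).
#' @param preference AP preference (self-similarity); `NULL` = median of
#'   the pairwise similarities.
#' @param max_iter,conv_iter AP iteration budget and convergence window.
#' @param spatial_weight feature weight for spatial coordinates (per mm).
#' @param intensity_weight feature weight for intensity; `NULL` = one SUV
#'   unit weighted like one voxel diagonal.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(fraction = 0.41, damping = 0.5,
                                preference = NULL, max_iter = 200L,
                                conv_iter = 15L, spatial_weight = 1,
                                intensity_weight = NULL) {
  stopifnot(fraction > 0, fraction < 1, damping >= 0.5, damping < 1,
            max_iter >= conv_iter)
  structure(list(fraction = fraction, damping = damping,
                 preference = preference, max_iter = as.integer(max_iter),
                 conv_iter = as.integer(conv_iter),
                 spatial_weight = spatial_weight,
                 intensity_weight = intensity_weight),
            class = "segmentation_params")
}

# logical array of voxels whose centers fall inside a world-mm box (2 x 3)
roi_mask <- function(grid, roi) {
  if (is.null(roi)) return(array(TRUE, grid$dims))
  inm <- lapply(1:3, function(a) {
    co <- axis_coords(grid, a)
    co >= roi[1, a] & co <= roi[2, a]
  })
  outer(outer(inm[[1]], inm[[2]], "&"), inm[[3]], "&")
}

#' Auto-derived ROI around a ground-truth structure
#'
#' The bounding box of the structure's analytic geometry dilated by twice
#' the reconstruction FWHM — a stand-in for the manually drawn region of
#' interest around each lesion.
#'
#' @param truth a `ground_truth`.
#' @param labels insert label(s) the ROI should enclose.
#' @param fwhm reconstruction FWHM in mm.
#' @return 2 x 3 world-mm box (rows lo, hi).
#' @export
auto_roi <- function(truth, labels, fwhm) {
  ins <- truth$spec$inserts
  sel <- ins[vapply(ins, function(p) p$label %in% labels, TRUE)]
  if (length(sel) == 0) stop("no insert matches the requested labels")
  boxes <- lapply(sel, prim_bbox)
  lo <- do.call(pmin, lapply(boxes, function(b) b[1, ])) - 2 * fwhm
  hi <- do.call(pmax, lapply(boxes, function(b) b[2, ])) + 2 * fwhm
  rbind(lo = lo, hi = hi)
}

#' Threshold segmentation of the metabolic active tumor volume
#'
#' MATV = voxels inside the ROI whose value is `>= fraction x` the ROI
#' maximum (boundary inclusive, so a constant-valued ROI selects the whole
#' ROI). All connected components inside the ROI are retained; use
#' [connected_components()] to split multi-lesion ROIs.
#'
#' @param image an [image3d()].
#' @param roi 2 x 3 world-mm box, or `NULL` for the whole image.
#' @param fraction threshold fraction of the ROI max (default 0.41).
#' @return logical mask array on the image grid.
#' @export
threshold_matv <- function(image, roi = NULL, fraction = 0.41) {
  stopifnot(inherits(image, "image3d"), fraction > 0, fraction < 1)
  rm_ <- roi_mask(image$grid, roi)
  if (!any(rm_)) stop("ROI does not intersect the image")
  mx <- max(image$values[rm_])
  if (mx <= 0) stop("ROI max is not positive; nothing to segment")
  rm_ & image$values >= fraction * mx
}

#' Connected components of a binary mask (26-connected)
#'
#' @param mask logical 3D array.
#' @return integer label array; components are numbered by voxel count,
#'   descending (1 = largest). Attribute `n` carries the component count.
#' @export
connected_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  labels <- array(0L, d)
  nextlab <- 0L
  todo <- which(mask)
  for (seed in todo) {
    if (labels[seed] != 0L) next
    nextlab <- nextlab + 1L
    labels[seed] <- nextlab
    frontier <- matrix(arrayInd(seed, d), ncol = 3)
    while (nrow(frontier) > 0) {
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
        sweep(frontier, 2, off[k, ], "+")
      }))
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0) break
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- unique(lin[mask[lin] & labels[lin] == 0L])
      if (length(new) == 0) break
      labels[new] <- nextlab
      frontier <- arrayInd(new, d)
    }
  }
  # renumber by size, descending
  sizes <- tabulate(labels[labels > 0L], nbins = nextlab)
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(nextlab); remap[ord] <- seq_len(nextlab)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  attr(labels, "n") <- nextlab
  labels
}

#' Affinity-propagation clustering
#'
#' Exemplar-based clustering by responsibility/availability message passing
#' with damping. Similarity is the negative squared Euclidean distance in
#' the supplied feature space; the preference (self-similarity) controls how
#' many exemplars emerge and defaults to the median pairwise similarity.
#' Fully deterministic: no random initialization, ties broken toward the
#' lower index.
#'
#' @param features numeric n x d matrix of feature vectors (rows = points).
#' @param preference scalar preference; `NULL` = median similarity.
#' @param damping damping factor in \[0.5, 1).
#' @param max_iter iteration budget.
#' @param conv_iter stop after the exemplar set is stable this many
#'   iterations.
#' @return list: `labels` (exemplar index per point, in 1..n), `exemplars`
#'   (sorted unique exemplar indices), `converged`, `iterations`.
#' @export
affinity_propagation <- function(features, preference = NULL, damping = 0.5,
                                 max_iter = 200L, conv_iter = 15L) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("non-finite features")
  n <- nrow(features)
  if (n < 1) stop("need at least one point")
  if (n == 1L) {
    return(list(labels = 1L, exemplars = 1L, converged = TRUE,
                iterations = 0L))
  }
  sq <- rowSums(features^2)
  S <- -(outer(sq, sq, "+") - 2 * tcrossprod(features))
  if (all(abs(S) < 1e-12)) {                 # all points identical
    return(list(labels = rep(1L, n), exemplars = 1L, converged = TRUE,
                iterations = 0L))
  }
  if (is.null(preference)) preference <- stats::median(S[row(S) != col(S)])
  diag(S) <- preference
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  old_ex <- integer(0); stable <- 0L; it <- 0L
  idx <- seq_len(n)
  # messages relax geometrically with factor `damping`, so both the burn-in
  # and the stability window are measured in relaxation units: at damping
  # 0.9 the dynamics are 5x slower than at the reference 0.5
  burn_in <- if (damping > 0) ceiling(log(0.01) / log(damping)) else 0L
  stable_needed <- ceiling(conv_iter * (1 - 0.5) / (1 - damping))
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    m1_col <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, m1_col)]
    AS2 <- AS; AS2[cbind(idx, m1_col)] <- -Inf
    m2 <- AS2[cbind(idx, max.col(AS2, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(idx, m1_col)] <- S[cbind(idx, m1_col)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0); diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, old_ex)) stable <- stable + 1L else stable <- 0L
    old_ex <- ex
    if (it > burn_in && stable >= stable_needed && length(ex) > 0) break
  }
  ex <- old_ex
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  # refine: alternate point assignment and per-cluster exemplar choice
  # (the exemplar maximizing total intra-cluster similarity), as in the
  # reference formulation's final step; deterministic, usually 1-2 passes
  for (pass in 1:2) {
    lab_of <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
    lab_of[ex] <- ex
    ex <- sort(unique(vapply(unique(lab_of), function(e) {
      members <- which(lab_of == e)
      members[which.max(colSums(S[members, members, drop = FALSE]))]
    }, 0L)))
  }
  lab_of <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  lab_of[ex] <- ex                          # exemplars label themselves
  list(labels = as.integer(lab_of), exemplars = as.integer(ex),
       converged = stable >= stable_needed, iterations = it)
}

#' Two-tier target construction inside a MATV
#'
#' Runs affinity propagation on the MATV voxels (features: world mm
#' coordinates and intensity, each scaled by the configured weights) and
#' merges the resulting clusters into two tiers by mean uptake: the inner
#' high-uptake sub-volume collects clusters whose mean exceeds the MATV-wide
#' mean; the outer target is the full MATV — mirroring an inner boost volume
#' nested in an outer target. Deterministic; parameters are meant to be
#' frozen once and reused across grids and protocols.
#'
#' @param image an [image3d()].
#' @param matv logical MATV mask on the image grid (from
#'   [threshold_matv()]).
#' @param params a [segmentation_params()].
#' @return a `segmentation_result`: `matv`, `labels` (cluster label map),
#'   `inner` (logical mask), per-tier volumes (mL) and mean uptake,
#'   `heterogeneous` flag, and the AP diagnostics.
#' @export
build_targets <- function(image, matv, params = segmentation_params()) {
  stopifnot(inherits(image, "image3d"))
  matv <- array(as.logical(matv), dim(matv))
  if (!any(matv)) stop("empty MATV")
  g <- image$grid
  vv <- voxel_volume(g) / 1000
  n <- sum(matv)
  if (n < 2) {
    return(structure(list(matv = matv, labels = array(as.integer(matv), g$dims),
                          inner = array(FALSE, g$dims),
                          outer_volume_ml = n * vv, inner_volume_ml = 0,
                          outer_mean = mean(image$values[matv]),
                          inner_mean = NA_real_,
                          heterogeneous = FALSE, ap = NULL),
                     class = "segmentation_result"))
  }
  ijk <- which(matv, arr.ind = TRUE)
  xyz <- sweep(sweep(ijk - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  vals <- image$values[matv]
  iw <- params$intensity_weight
  if (is.null(iw)) iw <- sqrt(sum(g$spacing^2))
  feat <- cbind(xyz * params$spatial_weight, vals * iw)
  ap <- affinity_propagation(feat, preference = params$preference,
                             damping = params$damping,
                             max_iter = params$max_iter,
                             conv_iter = params$conv_iter)
  labmap <- array(0L, g$dims)
  cl <- match(ap$labels, ap$exemplars)
  labmap[matv] <- cl
  overall <- mean(vals)
  cl_means <- tapply(vals, cl, mean)
  hot <- as.integer(names(cl_means))[cl_means > overall]
  inner <- array(FALSE, g$dims)
  inner[matv] <- cl %in% hot
  heterogeneous <- any(inner) && !all(inner[matv])
  if (!heterogeneous) inner <- array(FALSE, g$dims)
  structure(list(matv = matv, labels = labmap, inner = inner,
                 outer_volume_ml = sum(matv) * vv,
                 inner_volume_ml = sum(inner) * vv,
                 outer_mean = overall,
                 inner_mean = if (any(inner)) mean(image$values[inner])
                              else NA_real_,
                 heterogeneous = heterogeneous, ap = ap),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> outer %.4g mL, inner %.4g mL (%s)\n",
              x$outer_volume_ml, x$inner_volume_ml,
              if (x$heterogeneous) "heterogeneous" else "homogeneous"))
  invisible(x)
}
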
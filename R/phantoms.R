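#' Analytic phantom primitives
#'
#' Primitives are the analytic building blocks of a digital phantom: each one
#' couples a simple solid (sphere, finite cylinder, or capsule/tube) with a
#' uniform activity concentration in Bq/mL. Nested primitives are resolved
#' innermost-wins: a primitive listed *later* in a [phantom_spec()] insert
#' list takes precedence where it overlaps an earlier one.
#'
#' @param center numeric triple, world mm.
#' @param radius radius in mm, `> 0`.
#' @param length full length of the cylindrical part in mm (cylinder/capsule).
#' @param axis unit direction of the cylinder axis (default +z).
#' @param conc activity concentration in Bq/mL, `>= 0`.
#' @param label structure name used in masks and reports.
#' @return A `primitive` object.
#' @name primitives
NULL

new_primitive <- function(kind, center, radius, half_length, axis, conc, label) {
  stopifnot(is.finite(radius), radius > 0, is.finite(conc), conc >= 0)
  center <- as.numeric(center); stopifnot(length(center) == 3L)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = kind, center = center, radius = radius,
                 half_length = half_length, axis = axis,
                 conc = conc, label = label),
            class = "primitive")
}

#' @rdname primitives
#' @export
prim_sphere <- function(center, radius, conc, label = "sphere") {
  new_primitive("sphere", center, radius, 0, c(0, 0, 1), conc, label)
}

#' @rdname primitives
#' @export
prim_cylinder <- function(center, radius, length, conc, label = "cylinder",
                          axis = c(0, 0, 1)) {
  stopifnot(length > 0)
  new_primitive("cylinder", center, radius, length / 2, axis, conc, label)
}

#' @rdname primitives
#' @export
prim_capsule <- function(center, radius, length, conc, label = "capsule",
                         axis = c(0, 0, 1)) {
  stopifnot(length >= 0)
  new_primitive("capsule", center, radius, length / 2, axis, conc, label)
}

#' Analytic volume of a primitive in mL
#' @param prim a primitive.
#' @return volume in mL.
#' @export
primitive_volume <- function(prim) {
  v_mm3 <- switch(prim$kind,
    sphere   = 4 / 3 * pi * prim$radius^3,
    cylinder = pi * prim$radius^2 * 2 * prim$half_length,
    capsule  = pi * prim$radius^2 * 2 * prim$half_length +
               4 / 3 * pi * prim$radius^3,
    stop("unknown primitive kind: ", prim$kind))
  v_mm3 / 1000
}

# membership of world points (n x 3 matrix) in a primitive
prim_contains <- function(prim, pts) {
  d <- sweep(pts, 2, prim$center)
  if (prim$kind == "sphere") {
    return(rowSums(d^2) <= prim$radius^2)
  }
  t <- drop(d %*% prim$axis)
  r2 <- rowSums(d^2) - t^2
  if (prim$kind == "cylinder") {
    return(abs(t) <= prim$half_length & r2 <= prim$radius^2)
  }
  # capsule: distance to the axis segment
  tc <- pmin(pmax(t, -prim$half_length), prim$half_length)
  r2seg <- rowSums(d^2) - 2 * t * tc + tc^2
  r2seg <= prim$radius^2
}

# tight axis-aligned bounding box of a primitive (mm)
prim_bbox <- function(prim) {
  u <- prim$axis
  reach <- switch(prim$kind,
    sphere   = rep(prim$radius, 3),
    cylinder = prim$half_length * abs(u) +
               prim$radius * sqrt(pmax(1 - u^2, 0)),
    capsule  = prim$half_length * abs(u) + prim$radius)
  rbind(lo = prim$center - reach, hi = prim$center + reach)
}

#' Phantom specification
#'
#' A phantom is a background region (one primitive with its concentration)
#' plus an ordered list of inserts. Later inserts are innermost and win where
#' primitives overlap. The spec is the source of analytic ground truth:
#' per-insert volumes come from closed-form geometry, not voxel counting.
#'
#' @param background a primitive carrying the background concentration.
#' @param inserts list of primitives, outermost first.
#' @param name phantom name.
#' @param nominal_volume_ml optional nominal background volume in mL (e.g.
#'   the physical phantom's fill volume when only a cropped region is
#'   modelled geometrically).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(background, inserts = list(), name = "phantom",
                         nominal_volume_ml = NULL) {
  stopifnot(inherits(background, "primitive"))
  for (ins in inserts) {
    stopifnot(inherits(ins, "primitive"))
    if (primitive_volume(ins) <= 0) stop("insert volume must be > 0")
    bb <- prim_bbox(ins)
    corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
    if (!all(prim_contains(background, corners))) {
      stop(sprintf("insert '%s' does not lie inside the background region",
                   ins$label))
    }
  }
  labs <- vapply(inserts, function(p) p$label, "")
  if (anyDuplicated(labs)) stop("insert labels must be unique")
  structure(list(background = background, inserts = inserts, name = name,
                 nominal_volume_ml = nominal_volume_ml),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> '%s': background %.4g kBq/mL, %d insert(s)\n",
              x$name, x$background$conc / 1000, length(x$inserts)))
  for (p in x$inserts) {
    cat(sprintf("  %-6s %-8s %.4g mL @ %.4g kBq/mL\n", p$label, p$kind,
                primitive_volume(p), p$conc / 1000))
  }
  invisible(x)
}

#' Uniform calibration cylinder
#'
#' The uniform cylinder used for the SUV calibration / uniformity procedure:
#' a single homogeneous volume whose concentration is the injected activity
#' divided by the fill volume.
#'
#' @param total_activity_mbq total activity in MBq, `> 0`.
#' @param volume_ml fill volume in mL, `> 0`.
#' @param radius cylinder radius in mm (length follows from the volume).
#' @return a [phantom_spec()] with no inserts; background concentration
#'   `total_activity_mbq / volume_ml` (in Bq/mL).
#' @examples
#' cyl <- make_uniform_cylinder(70, 6000)   # 11.67 kBq/mL
#' @export
make_uniform_cylinder <- function(total_activity_mbq, volume_ml, radius = 80) {
  if (!is.finite(total_activity_mbq) || total_activity_mbq <= 0) {
    stop("total activity must be > 0")
  }
  if (!is.finite(volume_ml) || volume_ml <= 0) stop("volume must be > 0")
  conc <- total_activity_mbq * 1e6 / volume_ml        # Bq/mL
  len <- volume_ml * 1000 / (pi * radius^2)           # mm
  bg <- prim_cylinder(c(0, 0, 0), radius, len, conc, label = "background")
  phantom_spec(bg, name = "uniform_cylinder", nominal_volume_ml = volume_ml)
}

#' Six-sphere image-quality phantom
#'
#' A NEMA-style body phantom: six fillable spheres in one axial plane on a
#' ring, at a fixed contrast over a uniform background. The standard sphere
#' set is 10/13/17/22/28/37 mm diameter on a 114.4 mm ring.
#'
#' @param background_conc background concentration in Bq/mL.
#' @param contrast sphere-to-background concentration ratio, `> 1`. A
#'   contrast of 1 makes the spheres indistinguishable from background and is
#'   rejected (downstream recovery coefficients would be undefined).
#' @param diameters_mm sphere diameters in mm.
#' @param ring_radius radius of the circle of sphere centers, mm.
#' @param nominal_volume_ml nominal fill volume recorded on the spec.
#' @return a [phantom_spec()] with one sphere insert per diameter, labelled
#'   `"D10"`, `"D13"`, ...
#' @export
make_nema_spheres <- function(background_conc, contrast = 10,
                              diameters_mm = c(10, 13, 17, 22, 28, 37),
                              ring_radius = 57.2,
                              nominal_volume_ml = 10000) {
  stopifnot(all(is.finite(diameters_mm)), all(diameters_mm > 0))
  if (!is.finite(contrast) || contrast <= 1) {
    stop("contrast must be > 1 (spheres must be distinguishable from background)")
  }
  n <- length(diameters_mm)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  centers <- cbind(ring_radius * cos(ang), ring_radius * sin(ang), 0)
  # reject overlapping spheres
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      gap <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (gap <= (diameters_mm[i] + diameters_mm[j]) / 2) {
        stop("sphere placement yields overlapping spheres")
      }
    }
  }
  reach <- ring_radius + max(diameters_mm) / 2
  bg <- prim_cylinder(c(0, 0, 0), reach + 20, max(diameters_mm) + 60,
                      background_conc, label = "background")
  inserts <- lapply(seq_len(n), function(i) {
    prim_sphere(centers[i, ], diameters_mm[i] / 2,
                contrast * background_conc,
                label = sprintf("D%g", diameters_mm[i]))
  })
  phantom_spec(bg, inserts, name = "six_sphere",
               nominal_volume_ml = nominal_volume_ml)
}

#' Anthropomorphic nested-insert phantom
#'
#' Two tumour surrogates in a uniform soft-tissue background: V1, a 0.3 mL
#' tube filled with 0.116 MBq, and a 2 mL vial V3 (0.1 MBq) hosting a second
#' 0.3 mL tube V2 to create heterogeneous uptake. V2's own concentration is
#' not fixed by the physical set-up description and defaults to twice the V3
#' concentration; the combined structure V2+V3 has analytic volume 2.3 mL.
#'
#' @param v1_activity_mbq activity in V1 (MBq).
#' @param v3_activity_mbq activity in V3 (MBq).
#' @param v1_volume_ml,v2_volume_ml,v3_volume_ml insert volumes (mL).
#' @param v2_conc V2 concentration in Bq/mL; default `2 *` V3 concentration.
#' @param background_conc background concentration in Bq/mL (default 3.3
#'   kBq/mL, a typical soft-tissue level, giving high tumour-to-background
#'   contrast over a homogeneous background).
#' @return a [phantom_spec()] with inserts `V1`, `V3`, `V2` (V2 last =
#'   innermost, nested in V3).
#' @export
make_insert_phantom <- function(v1_activity_mbq = 0.116,
                                v3_activity_mbq = 0.1,
                                v1_volume_ml = 0.3,
                                v2_volume_ml = 0.3,
                                v3_volume_ml = 2,
                                v2_conc = NULL,
                                background_conc = 3300) {
  conc_v1 <- v1_activity_mbq * 1e6 / v1_volume_ml
  conc_v3 <- v3_activity_mbq * 1e6 / v3_volume_ml
  if (is.null(v2_conc)) v2_conc <- 2 * conc_v3
  r1 <- 4; r3 <- 5; r2 <- 3.5
  v1 <- prim_cylinder(c(-20, 0, 0), r1, v1_volume_ml * 1000 / (pi * r1^2),
                      conc_v1, label = "V1")
  # the vial's outer geometry hosts the nested V2 tube on top of its own
  # v3_volume_ml of solution, so the V2+V3 structure totals 2.3 mL
  v3 <- prim_cylinder(c(20, 0, 0), r3,
                      (v3_volume_ml + v2_volume_ml) * 1000 / (pi * r3^2),
                      conc_v3, label = "V3")
  # V2 sits inside V3, offset toward the vial top
  v2 <- prim_cylinder(c(20, 0, 4), r2, v2_volume_ml * 1000 / (pi * r2^2),
                      v2_conc, label = "V2")
  bg <- prim_cylinder(c(0, 0, 0), 70, 120, background_conc,
                      label = "background")
  phantom_spec(bg, list(v1, v3, v2), name = "nested_inserts")
}

#' Default fine "truth" grid for a phantom
#'
#' A 1 mm isotropic grid (finer than both EARL protocol grids, so emulation
#' only ever degrades the truth) covering the inserts plus a margin, or the
#' full background when there are no inserts.
#'
#' @param spec a [phantom_spec()].
#' @param spacing isotropic spacing in mm (default 1).
#' @param margin margin around the insert bounding box in mm.
#' @return a [grid3d()].
#' @export
truth_grid <- function(spec, spacing = 1, margin = 15) {
  if (length(spec$inserts) == 0) {
    ext <- prim_bbox(spec$background)
  } else {
    boxes <- lapply(spec$inserts, prim_bbox)
    lo <- do.call(pmin, lapply(boxes, function(b) b[1, ])) - margin
    hi <- do.call(pmax, lapply(boxes, function(b) b[2, ])) + margin
    ext <- rbind(lo, hi)
  }
  grid_covering(ext, rep(spacing, 3))
}

# grow (delta > 0) or shrink (delta < 0) a primitive isotropically
prim_inflate <- function(prim, delta) {
  p <- prim
  p$radius <- prim$radius + delta
  if (prim$kind != "sphere") p$half_length <- prim$half_length + delta
  if (p$radius <= 0 || (prim$kind == "cylinder" && p$half_length <= 0)) {
    return(NULL)
  }
  p
}

# fractional occupancy of each grid voxel by a primitive, via supersampling;
# returns a full-grid array (zero outside the primitive's bounding box).
# Voxels whose center lies deeper than half a voxel diagonal inside
# (outside) the surface are set to 1 (0) without supersampling.
prim_occupancy <- function(prim, grid, supersampling) {
  ss <- as.integer(supersampling)
  occ <- array(0, grid$dims)
  bb <- prim_bbox(prim)
  idx <- lapply(1:3, function(a) {
    co <- axis_coords(grid, a)
    which(co >= bb[1, a] - grid$spacing[a] & co <= bb[2, a] + grid$spacing[a])
  })
  if (any(lengths(idx) == 0)) return(occ)
  pts <- as.matrix(expand.grid(axis_coords(grid, 1)[idx[[1]]],
                               axis_coords(grid, 2)[idx[[2]]],
                               axis_coords(grid, 3)[idx[[3]]]))
  half_diag <- sqrt(sum(grid$spacing^2)) / 2
  frac <- numeric(nrow(pts))
  inner <- prim_inflate(prim, -half_diag)
  deep <- if (is.null(inner)) rep(FALSE, nrow(pts)) else prim_contains(inner, pts)
  outer_p <- prim_inflate(prim, half_diag)
  near <- prim_contains(outer_p, pts) & !deep
  frac[deep] <- ss^3
  if (any(near)) {
    off1 <- ((seq_len(ss) - 0.5) / ss - 0.5)
    pn <- pts[near, , drop = FALSE]
    fn <- numeric(nrow(pn))
    for (ox in off1) for (oy in off1) for (oz in off1) {
      sub <- cbind(pn[, 1] + ox * grid$spacing[1],
                   pn[, 2] + oy * grid$spacing[2],
                   pn[, 3] + oz * grid$spacing[3])
      fn <- fn + prim_contains(prim, sub)
    }
    frac[near] <- fn
  }
  occ[idx[[1]], idx[[2]], idx[[3]]] <- array(frac / ss^3, lengths(idx))
  occ
}

#' Rasterize a phantom to a voxelized ground truth
#'
#' Each voxel receives the volume-weighted mean concentration over its
#' supersampled subvoxels (partial-volume-aware rasterization). Per-insert
#' binary masks use voxel-center membership — the same convention as
#' [voi_from_primitive()], and volume-unbiased — with overlaps resolved
#' innermost-wins, so masks are disjoint. Rasterization is deterministic.
#'
#' @param spec a [phantom_spec()].
#' @param grid target [grid3d()].
#' @param supersampling subvoxel samples per axis, `>= 1` (default 4).
#' @return a `ground_truth` object: `image` ([image3d()], Bq/mL), `masks`
#'   (named list of logical arrays), `volumes_ml` and `concentrations`
#'   (named analytic values per insert), `spec`, and `supersampling`.
#' @export
rasterize <- function(spec, grid, supersampling = 4) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "grid3d"))
  supersampling <- as.integer(supersampling)
  if (supersampling < 1) stop("supersampling must be >= 1")
  for (p in spec$inserts) {
    if (2 * p$radius < 2 * min(grid$spacing)) {
      warning(sprintf("grid too coarse to represent insert '%s' (< 2 voxels across)",
                      p$label))
    }
  }
  occ_bg <- prim_occupancy(spec$background, grid, supersampling)
  ins <- spec$inserts
  occ <- lapply(ins, prim_occupancy, grid = grid, supersampling = supersampling)
  # innermost (last) wins: walk inserts from inner to outer, claiming volume
  n <- length(ins)
  net <- vector("list", n)
  claimed <- array(0, grid$dims)
  for (i in rev(seq_len(n))) {
    net[[i]] <- pmax(occ[[i]] - claimed, 0)
    claimed <- claimed + net[[i]]
  }
  bg_net <- pmax(occ_bg - claimed, 0)
  values <- bg_net * spec$background$conc
  for (i in seq_len(n)) values <- values + net[[i]] * ins[[i]]$conc
  # masks: voxel-center membership with innermost-wins overlap resolution —
  # the same convention as analytic VOIs, and volume-unbiased (an occupancy
  # majority rule systematically undercounts convex solids, since a voxel
  # centered exactly on the surface covers slightly less than half)
  centers <- voxel_centers(grid)
  winner <- array(0L, grid$dims)
  for (i in seq_len(n)) {           # later (inner) inserts overwrite
    winner[prim_contains(ins[[i]], centers)] <- i
  }
  masks <- lapply(seq_len(n), function(i) winner == i)
  labs <- vapply(ins, function(p) p$label, "")
  names(masks) <- labs
  # analytic volumes net of nesting: an inner (later) primitive wholly
  # inside an outer one claims its geometric volume from the outer's
  volumes <- vapply(ins, primitive_volume, 0)
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    bb <- prim_bbox(ins[[j]])
    corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
    if (all(prim_contains(ins[[i]], corners))) {
      volumes[i] <- volumes[i] - primitive_volume(ins[[j]])
    }
  }
  concs <- vapply(ins, function(p) p$conc, 0)
  names(volumes) <- names(concs) <- labs
  structure(list(image = image3d(values, grid, unit = "Bq/mL"),
                 masks = masks, volumes_ml = volumes,
                 concentrations = concs, spec = spec,
                 supersampling = supersampling),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> phantom '%s', %d mask(s)\n",
              x$spec$name, length(x$masks)))
  print(x$image$grid)
  invisible(x)
}
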
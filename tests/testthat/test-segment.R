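test_that("two-level toy: 41% threshold selects exactly the lesion", {
  g <- toy_grid(c(10, 10, 10))
  vals <- array(1, g$dims)
  lesion <- array(FALSE, g$dims); lesion[4:6, 4:7, 5:6] <- TRUE
  vals[lesion] <- 10
  img <- image3d(vals, g, unit = "SUV")
  m <- threshold_matv(img, roi = NULL, fraction = 0.41)
  expect_identical(m, lesion)           # threshold 4.1 > background 1
})

test_that("constant-valued ROI selects the whole ROI (inclusive bound)", {
  g <- toy_grid(c(8, 8, 8))
  img <- image3d(array(2, g$dims), g, unit = "SUV")
  roi <- rbind(c(-2, -2, -2), c(2, 2, 2))
  m <- threshold_matv(img, roi, fraction = 0.41)
  expect_identical(m, earlbench:::roi_mask(g, roi))
})

test_that("thresholding is idempotent and monotone in the fraction", {
  img <- toy_image(c(10, 10, 10), seed = 31, unit = "SUV")
  sm <- gaussian_blur(img, 2, pad_value = 0)
  m1 <- threshold_matv(sm, NULL, 0.41)
  # idempotent: re-threshold the masked image with the same fraction
  masked <- image3d(sm$values * m1, sm$grid, unit = "SUV")
  expect_identical(threshold_matv(masked, NULL, 0.41), m1)
  # monotone: higher fraction never enlarges the MATV
  fr <- c(0.2, 0.35, 0.41, 0.6, 0.8)
  masks <- lapply(fr, function(f) threshold_matv(sm, NULL, f))
  for (i in seq_len(length(fr) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  }
  expect_error(threshold_matv(sm, rbind(c(99, 99, 99), c(100, 100, 100))),
               "ROI")
})

test_that("connected components agree with an independent flood-fill oracle", {
  flood_oracle <- function(mask) {           # scan-and-merge, 26-connected
    d <- dim(mask)
    lab <- array(0L, d); nxt <- 0L
    for (seed in which(mask)) {
      if (lab[seed] != 0L) next
      nxt <- nxt + 1L
      stack <- seed
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (lab[cur] != 0L) next
        lab[cur] <- nxt
        ijk <- arrayInd(cur, d)
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          q <- ijk + c(dx, dy, dz)
          if (all(q >= 1) && all(q <= d)) {
            ql <- q[1] + (q[2] - 1L) * d[1] + (q[3] - 1L) * d[1] * d[2]
            if (mask[ql] && lab[ql] == 0L) stack <- c(stack, ql)
          }
        }
      }
    }
    lab
  }
  for (seed in 1:4) {
    mask <- with_fixed_seed(seed, array(runif(8^3) < 0.2, c(8, 8, 8)))
    if (!any(mask)) next
    cc <- connected_components(mask)
    oc <- flood_oracle(mask)
    expect_equal(attr(cc, "n"), max(oc))
    # same partition up to relabeling
    for (l in seq_len(max(oc))) {
      expect_equal(length(unique(cc[oc == l])), 1L)
    }
    # sorted by size, descending
    sizes <- tabulate(cc[cc > 0])
    expect_true(all(diff(sizes) <= 0))
  }
  expect_error(connected_components(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("two disjoint spheres give two components; single voxel gives one", {
  g <- toy_grid(c(12, 12, 12))
  m <- array(FALSE, g$dims)
  m[2:4, 2:4, 2:4] <- TRUE; m[9:11, 9:11, 9:11] <- TRUE
  cc <- connected_components(m)
  expect_equal(attr(cc, "n"), 2L)
  s <- array(FALSE, g$dims); s[5, 5, 5] <- TRUE
  cs <- connected_components(s)
  expect_equal(attr(cs, "n"), 1L)
  expect_equal(volume_of(cs == 1L, g), voxel_volume(g) / 1000)
})

test_that("affinity propagation matches exhaustive exemplar search", {
  netsim <- function(S, pref, ex) {
    s <- length(ex) * pref
    for (i in setdiff(seq_len(nrow(S)), ex)) s <- s + max(S[i, ex])
    s
  }
  for (seed in 1:3) {
    pts <- with_fixed_seed(seed, rbind(
      matrix(rnorm(12, 0, 0.25), ncol = 2),
      matrix(rnorm(12, 5, 0.25), ncol = 2)))
    n <- nrow(pts)
    S <- -as.matrix(stats::dist(pts))^2
    pref <- stats::median(S[row(S) != col(S)])
    ap <- affinity_propagation(pts)
    expect_equal(length(ap$exemplars), 2L)
    expect_true(ap$converged)
    # exemplars sit one per blob
    expect_true(any(ap$exemplars <= 6) && any(ap$exemplars > 6))
    # exhaustive search over all non-empty exemplar subsets
    best <- -Inf
    for (k in 1:n) {
      cmb <- utils::combn(n, k)
      for (c in seq_len(ncol(cmb))) {
        best <- max(best, netsim(S, pref, cmb[, c]))
      }
    }
    expect_equal(netsim(S, pref, ap$exemplars), best, tolerance = 1e-9)
  }
})

test_that("affinity propagation degenerate and robustness cases", {
  # all identical points -> one cluster
  ap <- affinity_propagation(matrix(2, 6, 3))
  expect_equal(length(ap$exemplars), 1L)
  expect_equal(ap$labels, rep(1L, 6))
  # single point
  expect_equal(affinity_propagation(matrix(0, 1, 2))$labels, 1L)
  # damping 0.9 vs 0.5 agree on the two-blob toy
  pts <- with_fixed_seed(9, rbind(matrix(rnorm(10, 0, 0.2), ncol = 2),
                                  matrix(rnorm(10, 4, 0.2), ncol = 2)))
  a5 <- affinity_propagation(pts, damping = 0.5)
  a9 <- affinity_propagation(pts, damping = 0.9, max_iter = 1000)
  expect_identical(a5$labels, a9$labels)
  # deterministic
  expect_identical(affinity_propagation(pts)$labels,
                   affinity_propagation(pts)$labels)
  expect_error(affinity_propagation(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("build_targets splits the nested insert into coherent tiers", {
  gt <- cached_insert()
  bg <- gt$spec$background$conc
  rec <- emulate_recon(gt$image, earl_protocol("EARL2"), bg_value = bg)
  roi <- auto_roi(gt, c("V2", "V3"), fwhm = 5)
  matv <- threshold_matv(rec, roi, 0.41)
  # AP intensity features expect SUV-scale values (background ~ SUV 1)
  res <- build_targets(image3d(rec$values / bg, rec$grid, "SUV"), matv)
  expect_true(res$heterogeneous)
  expect_true(all(res$inner <= res$matv))       # inner tier inside the MATV
  expect_gt(res$inner_mean, res$outer_mean)
  # labels partition the MATV
  expect_true(all((res$labels > 0) == res$matv))
  # inner tier overlaps the true V2 with SC > 0.5 at EARL2 resolution
  sc <- shape_coefficient(res$inner, gt$masks$V2, rec$grid, gt$image$grid)
  expect_gt(sc, 0.5)
})

test_that("homogeneous lesions are flagged, tiny MATVs degrade gracefully", {
  g <- toy_grid(c(8, 8, 8))
  vals <- array(1, g$dims); vals[3:6, 3:6, 3:6] <- 10
  img <- image3d(vals, g, unit = "SUV")
  matv <- threshold_matv(img, NULL, 0.41)
  res <- build_targets(img, matv)
  expect_false(res$heterogeneous)
  expect_equal(res$inner_volume_ml, 0)
  # single-voxel MATV
  one <- array(FALSE, g$dims); one[4, 4, 4] <- TRUE
  r1 <- build_targets(img, one)
  expect_false(r1$heterogeneous)
  expect_equal(r1$outer_volume_ml, voxel_volume(g) / 1000)
  expect_error(build_targets(img, array(FALSE, g$dims)), "empty")
})

test_that("segmentation is fully deterministic end to end", {
  gt <- cached_insert(spacing = 2)
  rec <- emulate_recon(gt$image, earl_protocol("EARL1"),
                       bg_value = gt$spec$background$conc)
  roi <- auto_roi(gt, c("V2", "V3"), fwhm = 6)
  r1 <- build_targets(rec, threshold_matv(rec, roi, 0.41))
  r2 <- build_targets(rec, threshold_matv(rec, roi, 0.41))
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$inner, r2$inner)
})
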
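test_that("suv_stats on a constant field: max = mean = peak = c", {
  g <- toy_grid(c(9, 9, 9))
  img <- image3d(array(4.2, g$dims), g, unit = "SUV")
  v <- voi(array(TRUE, g$dims), g)
  s <- suv_stats(img, v, peak_diameter = 4)
  expect_equal(s$suvmax, 4.2)
  expect_equal(s$suvmean, 4.2)
  expect_equal(s$suvpeak, 4.2, tolerance = 1e-12)
})

test_that("suv_stats agrees with a brute-force enumeration oracle", {
  # oracle: loop every VOI voxel as candidate center, enumerate all image
  # voxels within the sphere radius in world mm, average
  brute <- function(img, mask, diam) {
    g <- img$grid
    cand <- which(mask, arr.ind = TRUE)
    best <- -Inf
    for (i in seq_len(nrow(cand))) {
      cw <- g$origin + (cand[i, ] - 1) * g$spacing
      tot <- 0; n <- 0
      for (x in 1:g$dims[1]) for (y in 1:g$dims[2]) for (z in 1:g$dims[3]) {
        pw <- g$origin + (c(x, y, z) - 1) * g$spacing
        if (sum((pw - cw)^2) <= (diam / 2)^2) {
          tot <- tot + img$values[x, y, z]; n <- n + 1
        }
      }
      if (n > 0) best <- max(best, tot / n)
    }
    list(max = max(img$values[mask]), mean = mean(img$values[mask]),
         peak = best)
  }
  for (seed in 1:3) {
    img <- toy_image(c(7, 6, 5), spacing = c(1.5, 2, 1), seed = seed,
                     unit = "SUV")
    mask <- array(FALSE, img$grid$dims)
    mask[2:5, 2:4, 2:4] <- TRUE
    v <- voi(mask, img$grid)
    s <- suv_stats(img, v, peak_diameter = 5)
    o <- brute(img, mask, 5)
    expect_equal(s$suvmax, o$max, tolerance = 1e-12)
    expect_equal(s$suvmean, o$mean, tolerance = 1e-12)
    expect_equal(s$suvpeak, o$peak, tolerance = 1e-12)
    expect_lte(s$suvpeak, s$suvmax)
    expect_lte(s$suvmean, s$suvmax)
  }
})

test_that("single hot voxel: peak = hot / N over the enumerated sphere", {
  g <- toy_grid(c(9, 9, 9))
  vals <- array(0, g$dims); vals[5, 5, 5] <- 90
  img <- image3d(vals, g, unit = "SUV")
  mask <- array(FALSE, g$dims); mask[5, 5, 5] <- TRUE
  s <- suv_stats(img, voi(mask, g), peak_diameter = 4)
  # 4 mm sphere on a 1 mm grid: offsets with |d| <= 2 -> 33 voxels
  n_sphere <- sum(rowSums(as.matrix(expand.grid(-2:2, -2:2, -2:2))^2) <= 4)
  expect_equal(s$suvpeak, 90 / n_sphere, tolerance = 1e-12)
})

test_that("empty VOI and grid mismatch are rejected", {
  g <- toy_grid(c(4, 4, 4))
  expect_error(voi(array(FALSE, g$dims), g), "empty")
  img <- toy_image(c(4, 4, 4))
  v <- voi(array(TRUE, c(5, 5, 5)), toy_grid(c(5, 5, 5)))
  expect_error(suv_stats(img, v), "share a grid")
})

test_that("recovery coefficients: identity on unblurred truth, monotone in size", {
  bg_conc <- 2000
  gt <- cached_nema(spacing = 1.5, supersampling = 2)
  # unblurred truth, analytic VOI: rc_max = 1 exactly (interior voxels hit
  # the true concentration)
  rc0 <- recovery_coefficients(gt$image, gt, voi_policy = "analytic",
                               peak_diameter = NULL)
  expect_equal(rc0$rc_max, rep(1, 6), tolerance = 1e-9)
  # blurred: RC strictly within (background/actual, 1] and monotone with
  # sphere diameter for both protocols
  for (proto in list(earl_protocol("EARL1"), earl_protocol("EARL2"))) {
    rec <- emulate_recon(gt$image, proto, bg_value = bg_conc)
    rc <- recovery_coefficients(rec, gt, voi_policy = "analytic",
                                peak_diameter = NULL)
    expect_true(all(rc$rc_mean > bg_conc / 20000))
    expect_true(all(rc$rc_max <= 1 + 1e-9))
    ord <- order(gt$volumes_ml[rc$label])     # ascending diameter
    expect_true(all(diff(rc$rc_mean[ord]) > 0))
    expect_true(all(diff(rc$rc_max[ord]) > 0))
  }
})

test_that("check_limits: inclusive bounds and range flags", {
  rec <- data.frame(label = c("a", "b", "c", "d"),
                    rc_mean = c(0.35, 0.27, 0.43, 0.65))
  out <- check_limits(rec, rc_limits("EARL1"))
  expect_equal(out$status, c("in", "in", "in", "above"))
  expect_false(attr(out, "verdict"))
  out2 <- check_limits(rec[1:3, ], rc_limits("EARL1"))
  expect_true(attr(out2, "verdict"))
  out3 <- check_limits(data.frame(label = "x", rc_mean = 0.65),
                       rc_limits("EARL2"))
  expect_equal(out3$status, "above")
  expect_equal(check_limits(data.frame(label = "x", rc_mean = 0.38),
                            rc_limits("EARL2"))$status, "below")
})

test_that("uniformity check enforces the +-10% window around SUV 1", {
  g <- toy_grid(c(6, 6, 6))
  v <- voi(array(TRUE, g$dims), g)
  mk <- function(x) image3d(array(x, g$dims), g, unit = "SUV")
  expect_true(uniformity_check(mk(1.0), v)$pass)
  expect_true(uniformity_check(mk(1.05), v)$pass)
  expect_false(uniformity_check(mk(1.2), v)$pass)
  expect_error(uniformity_check(image3d(array(1, g$dims), g), v), "SUV")
})
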
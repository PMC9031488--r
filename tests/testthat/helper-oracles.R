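# independent brute-force oracles, kept free of the package's own code paths

# point evaluation of the three interpolants by direct per-point arithmetic
oracle_point <- function(img, p, method) {
  g <- img$grid
  u <- (p - g$origin) / g$spacing + 1
  ns <- g$dims
  if (method == "nearest") {
    j <- pmin(pmax(ceiling(u - 0.5), 1), ns)
    return(img$values[j[1], j[2], j[3]])
  }
  if (method == "linear") {
    uc <- pmin(pmax(u, 1), ns)
    j0 <- pmin(floor(uc), ns - 1)
    w <- uc - j0
    s <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      s <- s + wt * img$values[j0[1] + dx, j0[2] + dy, j0[3] + dz]
    }
    return(s)
  }
  # spline: nested per-axis 1D natural cubic splines on mirror-padded
  # samples (axis order z, then y, then x)
  pad <- 3
  mirror <- function(i, n) {
    per <- 2 * (n - 1)
    i <- (i - 1) %% per
    ifelse(i >= n - 1, per - i, i) + 1
  }
  ev <- function(y, n, at) {
    pp <- (1 - pad):(n + pad)
    stats::splinefun(pp, y[mirror(pp, n)], method = "natural")(
      min(max(at, 1 - pad), n + pad))
  }
  vy <- matrix(0, ns[1], ns[2])
  for (i in 1:ns[1]) for (j in 1:ns[2]) {
    vy[i, j] <- ev(img$values[i, j, ], ns[3], u[3])
  }
  vx <- numeric(ns[1])
  for (i in 1:ns[1]) vx[i] <- ev(vy[i, ], ns[2], u[2])
  ev(vx, ns[1], u[1])
}

# net similarity of an exemplar set (affinity-propagation objective)
ap_netsim <- function(S, pref, ex) {
  s <- length(ex) * pref
  for (i in setdiff(seq_len(nrow(S)), ex)) s <- s + max(S[i, ex])
  s
}

# cached phantom rasterizations shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached_nema <- function(spacing, supersampling) {
  key <- sprintf("nema_%g_%d", spacing, supersampling)
  if (is.null(.fixture_cache[[key]])) {
    spec <- make_nema_spheres(2000, contrast = 10)
    .fixture_cache[[key]] <- rasterize(
      spec, truth_grid(spec, spacing = spacing, margin = 12),
      supersampling = supersampling)
  }
  .fixture_cache[[key]]
}

cached_insert <- function(spacing = 1, supersampling = 4) {
  key <- sprintf("insert_%g_%d", spacing, supersampling)
  if (is.null(.fixture_cache[[key]])) {
    spec <- make_insert_phantom()
    .fixture_cache[[key]] <- rasterize(
      spec, truth_grid(spec, spacing = spacing),
      supersampling = supersampling)
  }
  .fixture_cache[[key]]
}
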
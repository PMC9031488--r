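#' Reconstruction protocol presets
#'
#' A reconstruction protocol bundles the emulation parameters of one
#' harmonized PET reconstruction: an isotropic Gaussian point-spread FWHM, a
#' target voxel grid spacing, an optional noise level and a seed. The vendor
#' iterative algorithms (OSEM / PSF-based) are deliberately replaced by a
#' single Gaussian-kernel surrogate: total resolution is the one tunable.
#'
#' Presets: `EARL1` = FWHM 6 mm on a 3.1819 x 3.1819 x 5 mm^3 grid;
#' `EARL2` = FWHM 5 mm on a 1.5910 x 1.5910 x 1.5 mm^3 grid.
#'
#' @param name protocol name (`"EARL1"`, `"EARL2"`, or custom).
#' @param psf_fwhm isotropic Gaussian FWHM in mm, `>= 0`.
#' @param spacing target grid spacing in mm (triple).
#' @param noise_sigma zero-mean Gaussian noise standard deviation as a
#'   fraction of the background concentration; 0 (default) disables noise.
#' @param seed integer seed used when noise is enabled.
#' @return A `recon_protocol` object.
#' @examples
#' earl_protocol("EARL2")
#' @export
recon_protocol <- function(name, psf_fwhm, spacing, noise_sigma = 0,
                           seed = 1L) {
  stopifnot(is.finite(psf_fwhm), psf_fwhm >= 0, noise_sigma >= 0)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(name = name, psf_fwhm = psf_fwhm, spacing = spacing,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "recon_protocol")
}

#' @rdname recon_protocol
#' @export
earl_protocol <- function(name = c("EARL1", "EARL2"), noise_sigma = 0,
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
    EARL1 = recon_protocol("EARL1", 6, c(3.1819, 3.1819, 5),
                           noise_sigma, seed),
    EARL2 = recon_protocol("EARL2", 5, c(1.5910, 1.5910, 1.5),
                           noise_sigma, seed))
}

#' @export
print.recon_protocol <- function(x, ...) {
  cat(sprintf("<recon_protocol> %s: FWHM %.4g mm, grid %.4g x %.4g x %.4g mm, noise %.3g\n",
              x$name, x$psf_fwhm, x$spacing[1], x$spacing[2], x$spacing[3],
              x$noise_sigma))
  invisible(x)
}

# apply a 1D kernel along one array axis with constant padding
conv_axis <- function(arr, kernel, axis, pad_value) {
  p <- (length(kernel) - 1L) / 2L
  if (p == 0L) return(arr * kernel)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  mp <- rbind(matrix(pad_value, p, ncol(m)), m, matrix(pad_value, p, ncol(m)))
  # convolution matrix row i picks padded rows i..i+2p
  K <- matrix(0, n, n + 2L * p)
  for (j in seq_along(kernel)) {
    K[cbind(seq_len(n), seq_len(n) + j - 1L)] <- kernel[j]
  }
  out <- K %*% mp
  aperm(array(out, d[perm]), order(perm))
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  p <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-p, p)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian blur of an image (separable, constant padding)
#'
#' @param image an [image3d()].
#' @param fwhm isotropic FWHM in mm; `sigma = fwhm / 2.3548`.
#' @param pad_value constant used beyond the field edge (phantom background
#'   level; 0 for air).
#' @return blurred [image3d()] on the same grid.
#' @export
gaussian_blur <- function(image, fwhm, pad_value = 0) {
  stopifnot(inherits(image, "image3d"), fwhm >= 0)
  if (fwhm == 0) return(image)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  vals <- image$values
  for (a in 1:3) {
    vals <- conv_axis(vals, gauss_kernel(sigma / image$grid$spacing[a]),
                      a, pad_value)
  }
  image3d(vals, image$grid, image$unit)
}

# per-axis interval-overlap weight matrix (rows: target voxels, cols: source)
overlap_matrix <- function(src_c, src_sp, tgt_c, tgt_sp) {
  slo <- src_c - src_sp / 2; shi <- src_c + src_sp / 2
  tlo <- tgt_c - tgt_sp / 2; thi <- tgt_c + tgt_sp / 2
  pmax(outer(thi, shi, pmin) - outer(tlo, slo, pmax), 0)
}

#' Volume-averaging (box-mean) resampling to a coarser grid
#'
#' Each target voxel takes the volume-weighted mean of the source voxels its
#' footprint overlaps — the tensor product of per-axis interval overlaps.
#' This represents detector binning and preserves total activity over the
#' covered extent. Target voxels with no source overlap take `fill`.
#'
#' @param image an [image3d()].
#' @param target a [grid3d()].
#' @param fill value for target voxels outside the source extent.
#' @return [image3d()] on `target`.
#' @export
box_resample <- function(image, target, fill = 0) {
  stopifnot(inherits(image, "image3d"), inherits(target, "grid3d"))
  g <- image$grid
  W <- lapply(1:3, function(a) {
    ov <- overlap_matrix(axis_coords(g, a), g$spacing[a],
                         axis_coords(target, a), target$spacing[a])
    rs <- rowSums(ov)
    covered <- rs > 0
    ov[covered, ] <- ov[covered, , drop = FALSE] / rs[covered]
    attr(ov, "covered") <- covered
    ov
  })
  vals <- image$values
  d <- dim(vals)
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(vals, perm), nrow = d[a])
    out <- W[[a]] %*% m
    d[a] <- nrow(W[[a]])
    vals <- aperm(array(out, c(d[a], dim(vals)[setdiff(1:3, a)])), order(perm))
  }
  covered <- outer(outer(attr(W[[1]], "covered"), attr(W[[2]], "covered"),
                         "&"), attr(W[[3]], "covered"), "&")
  vals[!covered] <- fill
  image3d(vals, target, image$unit)
}

#' Emulate a harmonized PET reconstruction
#'
#' Resolution degradation by isotropic Gaussian blurring on the fine truth
#' grid, then volume-averaging resampling to the protocol grid (blurring
#' first avoids aliasing small structures), optional zero-mean Gaussian
#' noise, and clipping at zero. The truth grid must be at least as fine as
#' the protocol grid on every axis: a finer protocol grid would fabricate
#' resolution that was never simulated.
#'
#' @param truth an [image3d()] activity map on a fine grid.
#' @param protocol a [recon_protocol()].
#' @param bg_value background concentration used for edge padding and as the
#'   noise-level reference; defaults to 0 (air beyond the field edge).
#' @return reconstructed [image3d()] on the protocol grid.
#' @export
emulate_recon <- function(truth, protocol, bg_value = 0) {
  stopifnot(inherits(truth, "image3d"), inherits(protocol, "recon_protocol"))
  if (any(truth$grid$spacing > protocol$spacing + 1e-9)) {
    stop("truth grid is coarser than the protocol grid on some axis; ",
         "emulation must never upsample")
  }
  out <- gaussian_blur(truth, protocol$psf_fwhm, pad_value = bg_value)
  target <- grid_covering(truth$grid, protocol$spacing)
  out <- box_resample(out, target, fill = bg_value)
  if (protocol$noise_sigma > 0) {
    ref <- if (bg_value > 0) bg_value else mean(out$values)
    vals <- out$values + with_seed(protocol$seed, {
      array(stats::rnorm(length(out$values), sd = protocol$noise_sigma * ref),
            dim(out$values))
    })
    out <- image3d(pmax(vals, 0), out$grid, out$unit)
  } else {
    out <- image3d(pmax(out$values, 0), out$grid, out$unit)
  }
  out
}

# run code with a fixed RNG seed without disturbing the global stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' SUV calibration
#'
#' Body-weight convention: `SUV = concentration[Bq/mL] / (injected[Bq] /
#' mass[g])`, assuming unit density (1 g/mL). A uniform phantom whose
#' concentration equals activity/volume and whose mass is volume x 1 g/mL
#' therefore reads SUV = 1 everywhere.
#'
#' @param activity_mbq injected (decay-corrected) activity in MBq, `> 0`.
#' @param mass_kg normalization mass in kg (patient weight or phantom fill
#'   mass), `> 0`.
#' @return a `suv_calibration` object.
#' @export
suv_calibration <- function(activity_mbq, mass_kg) {
  if (!is.finite(activity_mbq) || activity_mbq <= 0) {
    stop("injected activity must be > 0")
  }
  if (!is.finite(mass_kg) || mass_kg <= 0) stop("mass must be > 0")
  structure(list(activity_mbq = activity_mbq, mass_kg = mass_kg),
            class = "suv_calibration")
}

#' Convert an activity-concentration image to SUV
#'
#' @param image an [image3d()] in Bq/mL.
#' @param cal a [suv_calibration()].
#' @return [image3d()] tagged `"SUV"`; linear rescaling only.
#' @examples
#' cal <- suv_calibration(70, 6)   # 70 MBq in a 6 kg (6 L) phantom
#' @export
to_suv <- function(image, cal) {
  stopifnot(inherits(image, "image3d"), inherits(cal, "suv_calibration"))
  if (image$unit == "SUV") stop("image is already in SUV units")
  f <- cal$mass_kg * 1000 / (cal$activity_mbq * 1e6)
  image3d(image$values * f, image$grid, unit = "SUV")
}
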
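#' Minimal NIfTI-1 image input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii`, `.nii.gz`) with
#' axis-aligned geometry — sufficient for the package's images, masks and
#' label maps. Values are stored as float64 (numeric images; bit-exact
#' round trip) or int32 (label maps); uint8/int16/int32/float32/float64
#' inputs are accepted on read. Rotated or oblique orientations and
#' non-uniform slice spacing are rejected with a clear message. The unit
#' tag travels in the header `descrip` field as `unit=<tag>`.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param image an [image3d()] (for [write_image()]).
#' @param datatype `"auto"` (int32 for label/mask units, float64
#'   otherwise), `"float64"` or `"int32"`.
#' @return [read_image()] returns an [image3d()]; [write_image()] returns
#'   `path` invisibly.
#' @name nifti_io
NULL

nii_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

pad_char <- function(s, n) {
  r <- raw(n)
  b <- charToRaw(s)
  if (length(b) > 0) r[seq_len(min(n, length(b)))] <- b[seq_len(min(n, length(b)))]
  r
}

#' @rdname nifti_io
#' @export
write_image <- function(image, path, datatype = "auto") {
  stopifnot(inherits(image, "image3d"))
  if (datatype == "auto") {
    datatype <- if (image$unit %in% c("label", "mask")) "int32" else "float64"
  }
  dt_code <- switch(datatype, float64 = 64L, int32 = 8L,
                    stop("unsupported datatype: ", datatype))
  bitpix <- switch(datatype, float64 = 64L, int32 = 32L)
  g <- image$grid
  con <- nii_con(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(r) writeBin(r, con)
  w_i32(348L)                                   # sizeof_hdr
  w_raw(raw(35))                                # data_type, db_name, extents, session_error, regular
  w_raw(as.raw(0L))                             # dim_info
  w_i16(c(3L, g$dims, 1L, 1L, 1L, 1L))          # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)                  # intent_p1..3, intent_code
  w_i16(dt_code); w_i16(bitpix); w_i16(0L)      # datatype, bitpix, slice_start
  w_f32(c(1, g$spacing, 0, 0, 0, 0))            # pixdim[8]
  w_f32(352); w_f32(1); w_f32(0)                # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_raw(raw(1)); w_raw(as.raw(2L))   # slice_end, slice_code, xyzt_units (mm)
  w_f32(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_raw(pad_char(paste0("unit=", image$unit), 80))   # descrip
  w_raw(raw(24))                                # aux_file
  w_i16(0L); w_i16(1L)                          # qform_code, sform_code
  w_f32(c(0, 0, 0)); w_f32(g$origin)            # quatern, qoffset
  w_f32(c(g$spacing[1], 0, 0, g$origin[1]))     # srow_x
  w_f32(c(0, g$spacing[2], 0, g$origin[2]))     # srow_y
  w_f32(c(0, 0, g$spacing[3], g$origin[3]))     # srow_z
  w_raw(raw(16))                                # intent_name
  w_raw(pad_char("n+1", 4))                     # magic
  w_raw(raw(4))                                 # extension flag
  if (datatype == "int32") {
    writeBin(as.integer(round(image$values)), con, size = 4L,
             endian = "little")
  } else {
    writeBin(as.numeric(image$values), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_image <- function(path) {
  con <- nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("malformed NIfTI header: file too short")
  rd <- function(what, off, n, size, signed = TRUE) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little", signed = signed)
  }
  if (rd(integer(), 0, 1, 4) != 348L) {
    stop("malformed or big-endian NIfTI header (sizeof_hdr != 348)")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI header: bad magic")
  dim8 <- rd(integer(), 40, 8, 2)
  if (dim8[1] < 3 || any(dim8[2:4] < 1) || (dim8[1] > 3 && any(dim8[5:(dim8[1] + 1)] > 1))) {
    stop("only 3D volumes are supported")
  }
  dims <- dim8[2:4]
  datatype <- rd(integer(), 70, 1, 2)
  pixdim <- rd(numeric(), 76, 8, 4)
  vox_offset <- rd(numeric(), 108, 1, 4)
  scl_slope <- rd(numeric(), 112, 1, 4)
  scl_inter <- rd(numeric(), 116, 1, 4)
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  sform_code <- rd(integer(), 254, 1, 2)
  if (sform_code > 0) {
    srow <- rbind(rd(numeric(), 280, 4, 4), rd(numeric(), 296, 4, 4),
                  rd(numeric(), 312, 4, 4))
    R <- srow[, 1:3]
    offd <- R; diag(offd) <- 0
    if (any(abs(offd) > 1e-4 * max(abs(diag(R))))) {
      stop("rotated/oblique NIfTI orientations are not supported")
    }
    if (any(diag(R) <= 0)) {
      stop("flipped-axis NIfTI orientations are not supported")
    }
    spacing <- diag(R)
    origin <- srow[, 4]
  } else {
    spacing <- pixdim[2:4]
    origin <- c(0, 0, 0)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("malformed NIfTI header: non-positive voxel spacing")
  }
  n <- prod(dims)
  skip <- round(vox_offset) - 348L        # avoid seek(): unreliable on gz
  if (skip < 0) stop("malformed NIfTI header: vox_offset < 348")
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    "2"  = readBin(con, integer(), n, size = 1L, signed = FALSE),
    "4"  = readBin(con, integer(), n, size = 2L, endian = "little"),
    "8"  = readBin(con, integer(), n, size = 4L, endian = "little"),
    "16" = readBin(con, numeric(), n, size = 4L, endian = "little"),
    "64" = readBin(con, numeric(), n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(vals) < n) stop("malformed NIfTI file: truncated data")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  unit <- if (grepl("^unit=", descrip)) sub("^unit=", "", descrip) else "unknown"
  image3d(array(vals, dims), grid3d(dims, spacing, origin), unit = unit)
}
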
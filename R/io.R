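#' Read and write 8-bit panoramic images
#'
#' PNG files go through the \pkg{png} package; TIFF support is a minimal
#' built-in codec for uncompressed 8-bit greyscale/RGB baseline TIFF (the
#' format panoramic exports use), reading single- or multi-strip files and
#' writing single-strip little-endian ones. Images larger than the
#' ~120 Mpx limit of common desktop analysis tools trigger a warning but
#' are processed anyway.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param img a `grey_image`, `binary_mask` or `color_image` to write.
#' @param ... metadata passed on to [grey_image()] when reading.
#' @return `read_image()` returns a `grey_image` (or `color_image` for RGB
#'   input); `write_image()` returns `path` invisibly.
#' @name image_io
NULL

PIXEL_GUARD <- 120e6

warn_if_huge <- function(n_px) {
  if (n_px > PIXEL_GUARD) {
    warning(sprintf(
      "image has %.0f px, above the ~120 Mpx limit of common desktop tools; processing anyway",
      n_px))
  }
}

#' @rdname image_io
#' @export
read_image <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = read_tiff_baseline(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (ext == "png") arr <- round_half_up(arr * 255)
  warn_if_huge(length(arr) / max(1, dim(arr)[3], na.rm = TRUE))
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) {
    color_image(array(as.integer(arr[, , 1:3]), c(dim(arr)[1:2], 3L)))
  } else {
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    grey_image(matrix(as.integer(arr), nrow(arr), ncol(arr)), ...)
  }
}

#' @rdname image_io
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(img, "color_image")) {
    arr <- img$pixels
  } else {
    arr <- pixels_of(img)
  }
  warn_if_huge(nrow(arr) * ncol(arr))
  switch(ext,
         png = png::writePNG(arr / 255, path),
         tif = ,
         tiff = write_tiff_baseline(arr, path),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

# ---- minimal baseline TIFF ------------------------------------------------
# Uncompressed 8-bit grey or RGB, little-endian. Only what the pipeline
# needs: no preinstalled TIFF reader exists in this stack, and the files we
# exchange are our own exports, so a baseline subset is deliberate.

write_tiff_baseline <- function(arr, path) {
  rgb <- length(dim(arr)) == 3L
  h <- dim(arr)[1]; w <- dim(arr)[2]
  spp <- if (rgb) 3L else 1L
  # pixel data row-major, channels interleaved
  if (rgb) {
    px <- aperm(arr, c(3, 2, 1))       # channel, col, row -> interleave
    bytes <- as.raw(as.integer(px))
  } else {
    bytes <- as.raw(as.integer(t(arr)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)   # header, IFD at byte 8
  tags <- list(
    # tag, type (3 short, 4 long), count, value
    c(256L, 4L, 1L, w),                 # ImageWidth
    c(257L, 4L, 1L, h),                 # ImageLength
    c(258L, 3L, 1L, 8L),                # BitsPerSample (8 per sample)
    c(259L, 3L, 1L, 1L),                # Compression = none
    c(262L, 3L, 1L, if (rgb) 2L else 1L), # Photometric: RGB / BlackIsZero
    c(273L, 4L, 1L, NA),                # StripOffsets (patched below)
    c(277L, 3L, 1L, spp),               # SamplesPerPixel
    c(278L, 4L, 1L, h),                 # RowsPerStrip: one strip
    c(279L, 4L, 1L, length(bytes))      # StripByteCounts
  )
  if (rgb) tags[[3]] <- c(258L, 3L, 3L, NA)  # BitsPerSample needs 3 shorts
  n <- length(tags)
  ifd_size <- 2L + 12L * n + 4L
  extra_off <- 8L + ifd_size
  extra <- raw(0)
  data_off <- extra_off
  if (rgb) {                       # out-of-line BitsPerSample [8,8,8]
    bps_off <- extra_off
    extra <- writeBin(rep(8L, 3), raw(), size = 2, endian = "little")
    data_off <- extra_off + 6L
  }
  w2(n)
  for (tg in tags) {
    w2(tg[1]); w2(tg[2]); w4(tg[3])
    val <- tg[4]
    if (tg[1] == 273L) val <- data_off
    if (tg[1] == 258L && rgb) val <- bps_off
    if (tg[2] == 3L && tg[3] == 1L) { w2(val); w2(0L) } else w4(val)
  }
  w4(0L)                            # no next IFD
  if (length(extra)) writeBin(extra, con)
  writeBin(bytes, con)
  invisible(path)
}

read_tiff_baseline <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file", call. = FALSE)
  hdr <- rawToChar(raw[1:2])
  if (!hdr %in% c("II", "MM")) stop("not a TIFF file", call. = FALSE)
  endian <- if (hdr == "II") "little" else "big"
  rd <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size == 4)
  }
  if (rd(2, 2) != 42L) stop("not a TIFF file", call. = FALSE)
  ifd <- rd(4, 4)
  n <- rd(ifd, 2)
  tags <- list()
  for (i in seq_len(n) - 1L) {
    base <- ifd + 2L + 12L * i
    tag <- rd(base, 2); type <- rd(base + 2, 2); count <- rd(base + 4, 4)
    size <- c(1L, 1L, 2L, 4L)[type]    # BYTE ASCII SHORT LONG
    if (is.na(size)) next
    if (size * count <= 4L) {
      val <- rd(base + 8, size, count)
    } else {
      off <- rd(base + 8, 4)
      val <- rd(off, size, count)
    }
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing tag ", tag, call. = FALSE)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  if (any(need(258, 8L) != 8L)) stop("only 8-bit TIFF supported", call. = FALSE)
  if (need(259, 1L) != 1L) stop("only uncompressed TIFF supported",
                                call. = FALSE)
  spp <- need(277, 1L)
  offsets <- need(273)
  counts <- need(279, w * h * spp)
  bytes <- unlist(lapply(seq_along(offsets), function(i) {
    raw[(offsets[i] + 1):(offsets[i] + counts[i])]
  }))
  vals <- as.integer(bytes)
  if (spp == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0L, c(h, w, spp))
    px <- array(vals, c(spp, w, h))
    for (ch in seq_len(spp)) arr[, , ch] <- t(px[ch, , ])
    arr[, , 1:min(3L, spp), drop = FALSE]
  }
}

#' Write pipeline tables as CSV
#'
#' Thin wrappers fixing the column layout of the standard reports: area
#' reports (`sample_id`, `section_index`, `whole_px`, `whole_mm2`,
#' `epi_pct`, `stroma_pct`, `cellularity_pct`), histograms (`gv`, `abs`,
#' `rel_pct`) and profiles (`row`, `mean_gv`, `n_px`, `rel_pct`, `um`).
#'
#' @param x object to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path) {
  df <- if (is.data.frame(x)) x else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
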
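#' Construct an 8-bit greyscale panoramic image
#'
#' The elementary container of the pipeline: a height x width integer matrix
#' of grey values (GV) on the 0--255 scale, with the physical pixel size and
#' channel metadata attached. Row 1 is the top of the image, so profile
#' operations scan top to bottom down the matrix rows.
#'
#' @param pixels integer matrix of grey values in `[0, 255]`; rows are image
#'   rows from top to bottom.
#' @param resolution_um_per_px physical size of one pixel in micrometres
#'   (default `0.53937`, a 10x panoramic scan).
#' @param channel `"dapi"` for nuclear counterstain or `"marker"` for a
#'   primary-antibody signal.
#' @param marker_name free-text marker label (e.g. `"CD45"`).
#' @param sample_id free-text sample identifier.
#' @param section_index non-negative integer position in the serial stack.
#' @return an object of class `grey_image`.
#' @export
grey_image <- function(pixels, resolution_um_per_px = 0.53937,
                       channel = c("marker", "dapi"),
                       marker_name = "", sample_id = "", section_index = 0L) {
  channel <- match.arg(channel)
  pixels <- as_gv_matrix(pixels)
  if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1L ||
      !is.finite(resolution_um_per_px) || resolution_um_per_px <= 0) {
    stop("resolution_um_per_px must be a single positive number", call. = FALSE)
  }
  if (section_index < 0) stop("section_index must be >= 0", call. = FALSE)
  structure(
    list(pixels = pixels,
         resolution_um_per_px = resolution_um_per_px,
         channel = channel,
         marker_name = as.character(marker_name),
         sample_id = as.character(sample_id),
         section_index = as.integer(section_index)),
    class = "grey_image"
  )
}

#' Construct a binary mask
#'
#' Masks are binary images whose pixels take only the two grey values 0 and
#' 255, used for the whole-section footprint, the epithelial/stromal
#' compartments, threshold images and the extra-section background.
#'
#' @param pixels matrix containing only the values 0 and 255 (a logical
#'   matrix is accepted and mapped to 0/255).
#' @param role one of `"section"`, `"epithelial"`, `"stromal"`,
#'   `"threshold"`, `"background"`.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, role = c("section", "epithelial", "stromal",
                                         "threshold", "background")) {
  role <- match.arg(role)
  if (is.logical(pixels)) {
    storage.mode(pixels) <- "integer"
    pixels <- pixels * 255L
  }
  pixels <- as_gv_matrix(pixels)
  if (!all(pixels == 0L | pixels == 255L)) {
    stop("a binary mask may contain only the grey values 0 and 255",
         call. = FALSE)
  }
  structure(list(pixels = pixels, role = role), class = "binary_mask")
}

#' Construct an RGB colour image
#'
#' @param pixels height x width x 3 integer array with channel values in
#'   `[0, 255]`.
#' @return an object of class `color_image`.
#' @export
color_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be a height x width x 3 array", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != round(pixels))) {
    stop("RGB channel values must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels), class = "color_image")
}

# validate + coerce a grey-value matrix
as_gv_matrix <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (anyNA(pixels)) stop("pixels must not contain NA", call. = FALSE)
  if (any(pixels < 0) || any(pixels > 255) || any(pixels != round(pixels))) {
    stop("grey values must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  dimnames(pixels) <- NULL
  pixels
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image> %d x %d px, %.5f um/px, channel=%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$resolution_um_per_px,
              x$channel,
              if (nzchar(x$marker_name)) paste0(" (", x$marker_name, ")") else ""))
  cat(sprintf("  GV range %d..%d, mean %.2f\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, role=%s, white=%d px (%.2f%%)\n",
              nrow(x$pixels), ncol(x$pixels), x$role, sum(x$pixels == 255L),
              100 * mean(x$pixels == 255L)))
  invisible(x)
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<color_image> %d x %d px RGB\n", d[1], d[2]))
  invisible(x)
}

#' @export
dim.grey_image <- function(x) dim(x$pixels)

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

pixels_of <- function(x) {
  if (inherits(x, "grey_image") || inherits(x, "binary_mask")) return(x$pixels)
  if (is.matrix(x)) return(as_gv_matrix(x))
  stop("expected a grey_image, binary_mask or matrix", call. = FALSE)
}

check_same_dim <- function(a, b, what = "images") {
  da <- dim(pixels_of(a)); db <- dim(pixels_of(b))
  if (!identical(da, db)) {
    stop(sprintf("%s have different dimensions: %dx%d vs %dx%d",
                 what, da[1], da[2], db[1], db[2]), call. = FALSE)
  }
  invisible(TRUE)
}

check_gv_scalar <- function(t) {
  if (length(t) != 1L || is.na(t) || t < 0 || t > 255 || t != round(t)) {
    stop("threshold must be a single integer grey value in [0, 255]",
         call. = FALSE)
  }
  as.integer(t)
}
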
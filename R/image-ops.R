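#' Darken blend of two images
#'
#' Per-pixel minimum, the "Darken" compositing mode: `R = min(F, B)`.
#' Blending an image against a binary mask keeps the image only where the
#' mask is white, which is how compartment masking is done throughout the
#' pipeline.
#'
#' @param foreground,background `grey_image` (or `binary_mask`) objects of
#'   equal dimensions.
#' @return a `grey_image` carrying the foreground's metadata.
#' @export
blend_darken <- function(foreground, background) {
  check_same_dim(foreground, background)
  out <- pmin(pixels_of(foreground), pixels_of(background))
  rewrap_like(foreground, out)
}

#' Lighten blend of two images
#'
#' Per-pixel maximum, the "Lighten" compositing mode. Merging a marker
#' channel with its DAPI channel this way gives a single image whose nonzero
#' pixels cover everything either stain touched -- the first step of
#' whole-section mask construction.
#'
#' @param a,b `grey_image` (or `binary_mask`) objects of equal dimensions.
#' @return a `grey_image` carrying `a`'s metadata.
#' @export
blend_lighten <- function(a, b) {
  check_same_dim(a, b)
  out <- pmax(pixels_of(a), pixels_of(b))
  rewrap_like(a, out)
}

rewrap_like <- function(template, pixels) {
  if (inherits(template, "grey_image")) {
    grey_image(pixels,
               resolution_um_per_px = template$resolution_um_per_px,
               channel = template$channel,
               marker_name = template$marker_name,
               sample_id = template$sample_id,
               section_index = template$section_index)
  } else {
    grey_image(pixels)
  }
}

#' Binarize an image at a grey-value threshold
#'
#' Pixels with GV `>= t` become white (255), the rest black (0). The
#' threshold is inclusive, so `t = 1` whitens every nonzero pixel -- the
#' "lowest possible threshold" used to pick up any stained pixel when
#' building the whole-section mask.
#'
#' @param img a `grey_image`.
#' @param t integer grey value in `[0, 255]`.
#' @param role role recorded on the returned mask (default `"threshold"`).
#' @return a `binary_mask`.
#' @export
binarize <- function(img, t, role = "threshold") {
  t <- check_gv_scalar(t)
  binary_mask(pixels_of(img) >= t, role = role)
}

#' Invert a binary mask
#'
#' Swaps 0 and 255. Inverting twice is the identity.
#'
#' @param mask a `binary_mask` (a plain matrix of 0/255 is accepted).
#' @return a `binary_mask` with the same role.
#' @export
invert_mask <- function(mask) {
  role <- if (inherits(mask, "binary_mask")) mask$role else "threshold"
  px <- pixels_of(mask)
  if (!all(px == 0L | px == 255L)) {
    stop("invert_mask expects a binary image with values {0, 255}",
         call. = FALSE)
  }
  binary_mask(255L - px, role = role)
}

#' Desaturate an RGB image to 8-bit grey
#'
#' Converts colour to grey either by the plain channel average,
#' `round((R + G + B) / 3)`, or by the luminosity weights
#' `round(0.299 R + 0.587 G + 0.114 B)`. Different imaging software uses
#' different formulas and they disagree on saturated colours, which is why
#' both are offered; the choice is part of the measurement and should be
#' reported. Rounding is half-away-from-zero so output is bit-reproducible.
#'
#' @param img a `color_image`.
#' @param mode `"luminosity"` (default) or `"average"`.
#' @return a `grey_image`.
#' @export
desaturate <- function(img, mode = c("luminosity", "average")) {
  mode <- match.arg(mode)
  if (!inherits(img, "color_image")) stop("img must be a color_image",
                                          call. = FALSE)
  d <- dim(img$pixels)
  r <- matrix(img$pixels[, , 1], d[1], d[2])
  g <- matrix(img$pixels[, , 2], d[1], d[2])
  b <- matrix(img$pixels[, , 3], d[1], d[2])
  v <- switch(mode,
              average    = (r + g + b) / 3,
              luminosity = 0.299 * r + 0.587 * g + 0.114 * b)
  grey_image(round_half_up(v))
}

# round half away from zero (values here are always >= 0)
round_half_up <- function(x) floor(x + 0.5)

#' Classify grey values into the four-colour heatmap bins
#'
#' Assigns every pixel to one of five intensity classes used to visualize
#' the dynamic range of an IF signal: black 0--9 (sub-threshold), blue
#' 10--49 (weak), green 50--149 (moderate), red 150--254 (strong), yellow
#' 255 (saturated). The classes partition the 0--255 scale, so the per-class
#' counts always sum to the pixel total.
#'
#' @param img a `grey_image`.
#' @return a list with `labels` (factor matrix stored as integer matrix of
#'   class indices 1..5), `counts` (named integer vector), `rgb`
#'   (a `color_image` rendering) and `breaks` (the inclusive class bounds).
#' @export
heatmap_classify <- function(img) {
  px <- pixels_of(img)
  lower <- c(0L, 10L, 50L, 150L, 255L)
  upper <- c(9L, 49L, 149L, 254L, 255L)
  cls_names <- c("black", "blue", "green", "red", "yellow")
  idx <- findInterval(px, lower)      # partition => index in 1..5
  labels <- matrix(idx, nrow(px), ncol(px))
  counts <- tabulate(idx, nbins = 5L)
  names(counts) <- cls_names
  pal <- rbind(black  = c(0L, 0L, 0L),
               blue   = c(0L, 0L, 255L),
               green  = c(0L, 255L, 0L),
               red    = c(255L, 0L, 0L),
               yellow = c(255L, 255L, 0L))
  rgb_arr <- array(0L, c(nrow(px), ncol(px), 3L))
  for (ch in 1:3) rgb_arr[, , ch] <- matrix(pal[idx, ch], nrow(px), ncol(px))
  list(labels = labels,
       counts = counts,
       rgb = color_image(rgb_arr),
       breaks = data.frame(class = cls_names, lower = lower, upper = upper))
}

#' Generate the 750 x 150 px colour step-tablet
#'
#' A synthetic control image for checking how a desaturation algorithm maps
#' colours to grey: seven 50-column panels (white, green, red, blue, yellow,
#' cyan, magenta) separated by eight black gaps. Desaturating it and taking
#' a left-right column-mean profile must give exactly 255.0 over the white
#' panel and 0.0 over every gap regardless of the formula; the coloured
#' panels land at formula-dependent grey levels.
#'
#' @param panel_width columns per colour panel (default 50).
#' @param height tablet height in px (default 150).
#' @return a `color_image` of width `15 * panel_width` (750 x 150 at the
#'   defaults).
#' @export
make_step_tablet <- function(panel_width = 50L, height = 150L) {
  colors <- rbind(white   = c(255L, 255L, 255L),
                  green   = c(0L, 255L, 0L),
                  red     = c(255L, 0L, 0L),
                  blue    = c(0L, 0L, 255L),
                  yellow  = c(255L, 255L, 0L),
                  cyan    = c(0L, 255L, 255L),
                  magenta = c(255L, 0L, 255L))
  n_panels <- nrow(colors)
  # 15 blocks of `panel_width` columns: gaps and panels alternate starting
  # and ending with a black gap (8 gaps + 7 panels = 750 columns at 50).
  blocks <- vector("list", 2L * n_panels + 1L)
  k <- 1L
  blocks[[k]] <- matrix(0L, 3L, panel_width); k <- k + 1L
  for (p in seq_len(n_panels)) {
    blocks[[k]] <- matrix(colors[p, ], 3L, panel_width); k <- k + 1L
    blocks[[k]] <- matrix(0L, 3L, panel_width); k <- k + 1L
  }
  cols <- do.call(cbind, blocks)
  arr <- array(0L, c(height, ncol(cols), 3L))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(rep(cols[ch, ], each = height), height, ncol(cols))
  }
  color_image(arr)
}

#' Left-right column profile of a grey image
#'
#' Mean grey value of each 1 px-wide column, scanning left to right. Used to
#' verify the step-tablet and generally to profile horizontally laid-out
#' controls; the top-down row profile for tissue sections is
#' [td_profile()].
#'
#' @param img a `grey_image`.
#' @return numeric vector of length `width`.
#' @export
lr_profile <- function(img) colMeans(pixels_of(img))
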
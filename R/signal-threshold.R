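#' Background autofluorescence floor
#'
#' Scans binary threshold images at grey values 1, 2, ... and returns the
#' first threshold at which the extra-section background goes (almost)
#' completely black. At the default tolerance of 0 this is one grey value
#' above the brightest background pixel; a small positive tolerance ignores
#' that fraction of stray bright background pixels.
#'
#' @param img a `grey_image`.
#' @param background_mask `binary_mask` of pixels outside the section
#'   (role `"background"`; white = background).
#' @param tolerance_fraction fraction of background pixels allowed to
#'   survive the threshold, in `[0, 1)` (default 0).
#' @return integer grey value in 1..255.
#' @export
background_floor <- function(img, background_mask, tolerance_fraction = 0) {
  check_same_dim(img, background_mask)
  if (tolerance_fraction < 0 || tolerance_fraction >= 1) {
    stop("tolerance_fraction must be in [0, 1)", call. = FALSE)
  }
  bg <- pixels_of(img)[pixels_of(background_mask) == 255L]
  if (length(bg) == 0L) stop("background mask is empty", call. = FALSE)
  n <- length(bg)
  # surviving fraction at threshold t is mean(bg >= t); use the GV
  # distribution rather than re-binarizing 255 times
  counts <- tabulate(bg + 1L, nbins = 256L)          # counts at GV 0..255
  surviving <- rev(cumsum(rev(counts)))              # count >= g for g=0..255
  for (t in 1:255) {
    if (surviving[t + 1L] / n <= tolerance_fraction) return(as.integer(t))
  }
  stop("background contains GV 255 beyond tolerance; no floor exists",
       call. = FALSE)
}

#' Regression scan over candidate signal thresholds
#'
#' The core of signal thresholding: for each candidate grey value the ROI is
#' binarized, the top-down profiles of the original ROI and of the binary
#' threshold image are computed against the full ROI frame, and the original
#' profile is regressed on the binary profile. The candidate whose binary
#' image best co-localizes spatially with the weak IF signal -- the highest
#' coefficient of determination R^2 -- is selected as the IF signal
#' threshold (ties resolved toward the lowest grey value, retaining more
#' signal).
#'
#' @param roi a `grey_image`, typically a weak-signal region selected by
#'   [select_weak_roi()] or given in the configuration.
#' @param candidates integer grey values to scan (default `c(10, 20, 30,
#'   40, 50)`).
#' @return a `threshold_scan` object: `candidates`, `r2`, `p`,
#'   `selected_threshold`, and the per-candidate fits.
#' @export
threshold_scan <- function(roi, candidates = c(10L, 20L, 30L, 40L, 50L)) {
  if (length(candidates) == 0L) stop("candidates must be nonempty",
                                     call. = FALSE)
  candidates <- vapply(candidates, check_gv_scalar, integer(1))
  px <- pixels_of(roi)
  if (nrow(px) < 2L) stop("roi needs at least 2 rows", call. = FALSE)
  full <- binary_mask(matrix(TRUE, nrow(px), ncol(px)), role = "section")
  y <- td_profile(rewrap_like(roi, px), full)$row_means
  if (stats::var(y) == 0) stop("roi profile has zero variance", call. = FALSE)
  r2 <- p <- rep(NA_real_, length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    bin <- binarize(rewrap_like(roi, px), candidates[i])
    x <- td_profile(rewrap_like(roi, bin$pixels), full)$row_means
    if (stats::var(x) == 0) {
      warning(sprintf(
        "candidate %d gives a constant binary profile; excluded",
        candidates[i]))
      next
    }
    fit <- simple_regression(x, y)
    r2[i] <- fit$R2
    p[i] <- fit$p
    fits[[i]] <- fit
  }
  if (all(is.na(r2))) stop("all candidates degenerate; cannot select a threshold",
                           call. = FALSE)
  best <- which(r2 == max(r2, na.rm = TRUE))[1L]  # candidates scanned in
  # ascending order, so the first maximum is the lowest tied GV
  structure(
    list(candidates = candidates, r2 = r2, p = p,
         selected_threshold = candidates[best], fits = fits),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("<threshold_scan>\n")
  for (i in seq_along(x$candidates)) {
    cat(sprintf("  THRLD_%d: R2 = %s, p = %s%s\n", x$candidates[i],
                formatC(x$r2[i], digits = 4, format = "fg"),
                formatC(x$p[i], digits = 3, format = "g"),
                if (x$candidates[i] == x$selected_threshold) "  <- selected" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.threshold_scan <- function(x, ...) {
  data.frame(candidate = x$candidates, r2 = x$r2, p = x$p,
             selected = x$candidates == x$selected_threshold)
}

#' Auto-select a weak-signal region of interest
#'
#' The weak-signal ROI is chosen by eye in the manual protocol; for
#' reproducibility this helper slides a window over the image and returns
#' the in-section window maximizing the fraction of pixels in the
#' weak-signal grey-value band `[floor_gv, upper_gv]` minus the fraction
#' above it -- a region rich in weak signal and poor in strong signal,
#' which is what "a region containing weak IF signals" means in practice
#' (strong signal would dominate the profile variance and defeat the scan).
#'
#' @param img a `grey_image`.
#' @param section_mask `binary_mask` of the section.
#' @param floor_gv lower edge of the weak band (the background floor).
#' @param upper_gv upper edge of the weak band (default 50).
#' @param size window side length in px (default 128).
#' @param stride window step in px (default `size %/% 2`).
#' @return a list `x, y, w, h` (1-based top-left corner) plus `roi`, the
#'   cropped `grey_image`.
#' @export
select_weak_roi <- function(img, section_mask, floor_gv, upper_gv = 50L,
                            size = 128L, stride = size %/% 2L) {
  check_same_dim(img, section_mask)
  px <- pixels_of(img)
  inm <- pixels_of(section_mask) == 255L
  h <- nrow(px); w <- ncol(px)
  size <- min(size, h, w)
  weak <- (px >= floor_gv & px <= upper_gv) & inm
  bright <- (px > upper_gv) & inm
  signal <- (px >= floor_gv) & inm
  best <- NULL; best_score <- -Inf
  rows <- unique(c(seq(1L, h - size + 1L, by = stride), h - size + 1L))
  cols <- unique(c(seq(1L, w - size + 1L, by = stride), w - size + 1L))
  for (i in rows) for (j in cols) {
    ii <- i:(i + size - 1L); jj <- j:(j + size - 1L)
    if (sum(inm[ii, jj]) < size * size / 2) next  # mostly-background windows
    # the useful scan window mixes weak staining with unstained tissue
    # (half-covered) and avoids strong signal, whose single bright
    # structures would dominate the window profile's variance
    n <- size * size
    cov <- sum(signal[ii, jj]) / n
    score <- (sum(weak[ii, jj]) - 4 * sum(bright[ii, jj])) / n -
      2 * abs(cov - 0.5)
    if (score > best_score) { best_score <- score; best <- c(i, j) }
  }
  if (is.null(best)) stop("no window lies mostly inside the section",
                          call. = FALSE)
  crop <- px[best[1]:(best[1] + size - 1L), best[2]:(best[2] + size - 1L)]
  list(x = best[2], y = best[1], w = size, h = size,
       roi = rewrap_like(img, crop))
}

#' Apply the signal threshold to an image
#'
#' Zeros every pixel below the threshold while leaving supra-threshold
#' pixels untouched -- the "physical" exclusion of autofluorescence before
#' spatial-gradient profiling. Equivalent to darken-blending the image with
#' the inverted sub-threshold mask.
#'
#' @param img a `grey_image`.
#' @param t integer grey value in `[0, 255]`.
#' @return a `grey_image`.
#' @export
apply_threshold <- function(img, t) {
  t <- check_gv_scalar(t)
  px <- pixels_of(img)
  px[px < t] <- 0L
  rewrap_like(img, px)
}
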
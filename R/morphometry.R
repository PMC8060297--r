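#' Binary morphology on masks
#'
#' Dilation and erosion with a Euclidean disk of the given radius, computed
#' through an exact squared distance transform; closing is dilation followed
#' by erosion. `fill_holes()` whitens any black region not connected to the
#' image border (4-connectivity).
#'
#' @param mask a `binary_mask`.
#' @param radius_px disk radius in pixels (>= 0; 0 is a no-op).
#' @return a `binary_mask` with the same role.
#' @name morphology
NULL

#' @rdname morphology
#' @export
mask_dilate <- function(mask, radius_px) {
  stopifnot(radius_px >= 0)
  if (radius_px == 0) return(mask)
  fg <- pixels_of(mask) == 255L
  d2 <- .cpp_edt_sq(fg)
  binary_mask(d2 <= radius_px^2, role = mask$role)
}

#' @rdname morphology
#' @export
mask_erode <- function(mask, radius_px) {
  stopifnot(radius_px >= 0)
  if (radius_px == 0) return(mask)
  bg <- pixels_of(mask) != 255L
  d2 <- .cpp_edt_sq(bg)
  binary_mask(d2 > radius_px^2, role = mask$role)
}

#' @rdname morphology
#' @export
mask_close <- function(mask, radius_px) {
  mask_erode(mask_dilate(mask, radius_px), radius_px)
}

#' @rdname morphology
#' @export
fill_holes <- function(mask) {
  open <- pixels_of(mask) != 255L
  reachable <- .cpp_border_reachable(open)
  binary_mask(!(open & reachable), role = mask$role)
}

#' Build the whole-section area mask
#'
#' Reconstructs the footprint of the histological section from a marker
#' channel and its DAPI channel: the two panoramas are lighten-merged,
#' thresholded at the lowest possible grey value (1) so every stained pixel
#' turns white, then morphological closing bridges the remaining gaps at the
#' tissue/background interface (the automated stand-in for manually brushing
#' them shut), stray background speckle is discarded by keeping only the
#' largest connected white region (the automated magic-wand selection) and
#' enclosed holes are filled with pure white.
#'
#' @param marker,dapi `grey_image` objects of equal dimensions.
#' @param close_radius_px closing-disk radius in pixels (default 15).
#' @param keep_largest_only drop all but the largest connected component
#'   before hole filling (default TRUE). Disable when a section legitimately
#'   fragments into several pieces.
#' @return a `binary_mask` with role `"section"`. All-zero inputs yield an
#'   empty mask with a warning.
#' @export
build_section_mask <- function(marker, dapi, close_radius_px = 15L,
                               keep_largest_only = TRUE) {
  check_same_dim(marker, dapi)
  if (close_radius_px < 0) stop("close_radius_px must be >= 0", call. = FALSE)
  merged <- blend_lighten(marker, dapi)
  m <- binarize(merged, 1L, role = "section")
  if (!any(m$pixels == 255L)) {
    warning("both input images are all-zero; returning an empty section mask")
    return(m)
  }
  m <- mask_close(m, close_radius_px)
  if (keep_largest_only) m <- largest_component(m)
  fill_holes(m)
}

#' @rdname morphology
#' @export
largest_component <- function(mask) {
  keep <- .cpp_largest_component(pixels_of(mask) == 255L)
  binary_mask(keep, role = mask$role)
}

#' Split a section into epithelial and stromal compartments
#'
#' The epithelial mask (typically hand-drawn on the DAPI template, or taken
#' from the synthetic generator) is clipped to the section; the stromal
#' compartment is the section darken-blended with the inverted epithelial
#' mask. The two compartments partition the section footprint exactly.
#'
#' @param section `binary_mask` of the whole-section area.
#' @param epithelial_mask `binary_mask` of the epithelial compartment;
#'   pixels outside the section are cleared with a warning.
#' @param resolution_um_per_px pixel size in micrometres.
#' @return a `section_geometry` object: `section_mask`, `epithelial_mask`,
#'   `stromal_mask`, `resolution_um_per_px`.
#' @export
split_compartments <- function(section, epithelial_mask,
                               resolution_um_per_px = 0.53937) {
  check_same_dim(section, epithelial_mask)
  sec <- pixels_of(section)
  epi <- pixels_of(epithelial_mask)
  outside <- epi == 255L & sec != 255L
  if (any(outside)) {
    warning(sprintf("%d epithelial px outside the section mask were cleared",
                    sum(outside)))
    epi[outside] <- 0L
  }
  epi_mask <- binary_mask(epi, role = "epithelial")
  stroma <- blend_darken(binary_mask(sec, role = "section"),
                         invert_mask(epi_mask))
  structure(
    list(section_mask = binary_mask(sec, role = "section"),
         epithelial_mask = epi_mask,
         stromal_mask = binary_mask(stroma$pixels, role = "stromal"),
         resolution_um_per_px = resolution_um_per_px),
    class = "section_geometry"
  )
}

#' Histomorphometry of a section
#'
#' Whole-section area in px and mm^2 (one pixel covers
#' `(um_per_px / 1000)^2` mm^2) and compartment fraction areas as
#' percentages of the section area. Fractions are computed on the exact
#' pixel partition, so they sum to 100 before any rounding.
#'
#' @param geometry a `section_geometry` from [split_compartments()].
#' @param cellularity_pct optional DAPI cellularity to carry along.
#' @return a one-row `data.frame`: `whole_px`, `whole_mm2`, `epi_pct`,
#'   `stroma_pct`, `cellularity_pct`.
#' @export
measure_areas <- function(geometry, cellularity_pct = NA_real_) {
  stopifnot(inherits(geometry, "section_geometry"))
  sec_px <- sum(geometry$section_mask$pixels == 255L)
  if (sec_px == 0L) stop("section mask is empty; no area to measure",
                         call. = FALSE)
  epi_px <- sum(geometry$epithelial_mask$pixels == 255L)
  str_px <- sum(geometry$stromal_mask$pixels == 255L)
  mm_per_px <- geometry$resolution_um_per_px / 1000
  data.frame(
    whole_px = sec_px,
    whole_mm2 = sec_px * mm_per_px^2,
    epi_pct = 100 * epi_px / sec_px,
    stroma_pct = 100 * str_px / sec_px,
    cellularity_pct = cellularity_pct
  )
}

#' DAPI cellularity of a masked region
#'
#' The fraction of in-mask area covered by supra-threshold DAPI signal --
#' the expression domain of the nuclear counterstain, used as a proxy for
#' cell content instead of counting nuclei. Equivalent to summing the
#' relative grey-value histogram over the 10--255 scale at the default
#' threshold.
#'
#' @param dapi a `grey_image` of the DAPI channel.
#' @param mask reference `binary_mask` (whole section or one compartment).
#' @param t signal threshold grey value (default 10).
#' @return percentage in `[0, 100]`.
#' @export
cellularity <- function(dapi, mask, t = 10L) {
  t <- check_gv_scalar(t)
  check_same_dim(dapi, mask)
  inm <- pixels_of(mask) == 255L
  n <- sum(inm)
  if (n == 0L) stop("mask is empty; cellularity undefined", call. = FALSE)
  100 * sum(pixels_of(dapi)[inm] >= t) / n
}
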
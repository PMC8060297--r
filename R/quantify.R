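#' Grey-value histogram of a masked image
#'
#' Counts in-mask pixels at each of the 256 grey values and expresses each
#' count as a percentage of the reference (mask) area. The output always has
#' 256 bins regardless of image size, which is what makes histograms from
#' sections of different sizes directly comparable.
#'
#' @param img a `grey_image`.
#' @param mask reference `binary_mask`; only in-mask pixels are tallied and
#'   the mask area is the denominator of the relative counts.
#' @return a `gv_histogram` object: `gv` (0..255), `abs_counts`,
#'   `reference_area_px`, `rel_counts_pct`, `threshold` (NA until truncated).
#' @export
gv_histogram <- function(img, mask) {
  check_same_dim(img, mask)
  inm <- pixels_of(mask) == 255L
  area <- sum(inm)
  if (area == 0L) stop("mask is empty; histogram undefined", call. = FALSE)
  counts <- tabulate(pixels_of(img)[inm] + 1L, nbins = 256L)
  structure(
    list(gv = 0:255,
         abs_counts = counts,
         reference_area_px = area,
         rel_counts_pct = 100 * counts / area,
         threshold = NA_integer_),
    class = "gv_histogram"
  )
}

#' Truncate a histogram at the signal threshold
#'
#' Discards the reporting of bins below the grey-value threshold `t`
#' (autofluorescence), leaving `256 - t` values: 246 at the usual threshold
#' of 10. The reference area is unchanged, so relative counts keep their
#' meaning as percentages of the whole mask.
#'
#' @param hist a `gv_histogram`.
#' @param t integer grey value in `[0, 255]`.
#' @return a `gv_histogram` whose vectors cover `t..255` and whose
#'   `threshold` is `t`.
#' @export
truncate_histogram <- function(hist, t) {
  stopifnot(inherits(hist, "gv_histogram"))
  t <- check_gv_scalar(t)
  keep <- hist$gv >= t
  structure(
    list(gv = hist$gv[keep],
         abs_counts = hist$abs_counts[keep],
         reference_area_px = hist$reference_area_px,
         rel_counts_pct = hist$rel_counts_pct[keep],
         threshold = t),
    class = "gv_histogram"
  )
}

#' Expression domain from a histogram
#'
#' The percentage of the reference area covered by supra-threshold signal:
#' the sum of relative counts over grey values `t..255`.
#'
#' @param hist a `gv_histogram` (truncated or not).
#' @param t threshold grey value; defaults to the histogram's own threshold
#'   (or 0 if it has none).
#' @return percentage in `[0, 100]`.
#' @export
expression_domain <- function(hist, t = NULL) {
  stopifnot(inherits(hist, "gv_histogram"))
  if (is.null(t)) t <- if (is.na(hist$threshold)) 0L else hist$threshold
  t <- check_gv_scalar(t)
  sum(hist$rel_counts_pct[hist$gv >= t])
}

#' @export
print.gv_histogram <- function(x, ...) {
  cat(sprintf("<gv_histogram> %d bins (GV %d..%d), reference area %d px\n",
              length(x$gv), min(x$gv), max(x$gv), x$reference_area_px))
  if (!is.na(x$threshold)) cat(sprintf("  threshold GV %d\n", x$threshold))
  cat(sprintf("  expression domain over reported bins: %.2f%%\n",
              sum(x$rel_counts_pct)))
  invisible(x)
}

#' @export
as.data.frame.gv_histogram <- function(x, ...) {
  data.frame(gv = x$gv, abs = x$abs_counts, rel_pct = x$rel_counts_pct)
}

#' Top-down 2D plot profile
#'
#' The spatial-gradient summary: for every 1 px-wide row from the top to the
#' bottom of the panorama, the mean grey value over the pixels inside the
#' section mask. Using the binary whole-section image as the reference
#' removes the influence of background pixels on the row means. Positions
#' are calibrated to micrometres via the pixel size; the total scanning
#' distance spans the `H - 1` inter-row steps.
#'
#' @param img a `grey_image`.
#' @param section_mask reference `binary_mask`; rows with no in-section
#'   pixels get mean 0 and count 0.
#' @return a `td_profile` object: `row_means`, `in_section_counts`,
#'   `rel_pct` (% of the maximal row mean), `positions_um`,
#'   `total_distance_um`, plus resolution and marker metadata.
#' @export
td_profile <- function(img, section_mask) {
  check_same_dim(img, section_mask)
  px <- pixels_of(img)
  inm <- pixels_of(section_mask) == 255L
  if (!any(inm)) stop("section mask is empty; profile undefined", call. = FALSE)
  n_in <- rowSums(inm)
  sums <- rowSums(px * inm)
  means <- ifelse(n_in > 0, sums / n_in, 0)
  mx <- max(means)
  rel <- if (mx > 0) 100 * means / mx else means * 0
  res <- if (inherits(img, "grey_image")) img$resolution_um_per_px else 0.53937
  h <- nrow(px)
  structure(
    list(row_means = as.numeric(means),
         in_section_counts = as.integer(n_in),
         rel_pct = as.numeric(rel),
         positions_um = (seq_len(h) - 1) * res,
         total_distance_um = (h - 1) * res,
         resolution_um_per_px = res,
         marker_name = if (inherits(img, "grey_image")) img$marker_name else "",
         sample_id = if (inherits(img, "grey_image")) img$sample_id else ""),
    class = "td_profile"
  )
}

#' @export
print.td_profile <- function(x, ...) {
  cat(sprintf(
    "<td_profile> %d rows, %.5f um/px, total scanning distance %.1f um\n",
    length(x$row_means), x$resolution_um_per_px, x$total_distance_um))
  cat(sprintf("  row-mean GV range %.2f..%.2f\n",
              min(x$row_means), max(x$row_means)))
  invisible(x)
}

#' @export
as.data.frame.td_profile <- function(x, ...) {
  data.frame(row = seq_along(x$row_means),
             mean_gv = x$row_means,
             n_px = x$in_section_counts,
             rel_pct = x$rel_pct,
             um = x$positions_um)
}

#' Group comparison of morphometry scalars or expression-domain histograms
#'
#' Two layers of hypothesis testing are used in the pipeline and both live
#' here. Histomorphometric scalars (areas, fractions, cellularity) are
#' compared by a two-sample Student t-test at `alpha = 0.1`. Expression
#' domains are compared by one-way ANOVA at `alpha = 0.01`, where each
#' sample contributes its truncated relative histogram vector (246 values at
#' threshold 10) so that both the size of the domain and the intensity
#' distribution inform the test.
#'
#' @param groups a named list of groups; for `test = "t_test"` each group is
#'   a numeric vector of per-sample scalars, for `test = "anova"` each group
#'   is a list of `gv_histogram` objects (or numeric vectors) pooled within
#'   the group.
#' @param test `"t_test"` or `"anova"`.
#' @param alpha significance level; defaults to 0.1 for the t-test and 0.01
#'   for ANOVA.
#' @param var.equal use the pooled-variance Student t-test (default TRUE,
#'   which preserves the two-group identity `F = t^2` with ANOVA).
#' @return a `group_test_result`: `test`, `statistic`, `p_value`, `alpha`,
#'   `significant`, `df`.
#' @export
compare_groups <- function(groups, test = c("t_test", "anova"), alpha = NULL,
                           var.equal = TRUE) {
  test <- match.arg(test)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(alpha)) alpha <- if (test == "t_test") 0.1 else 0.01
  as_values <- function(g) {
    if (inherits(g, "gv_histogram")) return(g$rel_counts_pct)
    if (is.list(g)) return(unlist(lapply(g, as_values), use.names = FALSE))
    as.numeric(g)
  }
  vals <- lapply(groups, as_values)
  ns <- vapply(vals, length, integer(1))
  if (any(ns < 2L)) stop("every group needs at least 2 observations",
                         call. = FALSE)
  if (test == "t_test") {
    if (length(vals) != 2L) stop("t_test requires exactly 2 groups",
                                 call. = FALSE)
    if (stats::var(vals[[1]]) == 0 && stats::var(vals[[2]]) == 0 &&
        mean(vals[[1]]) == mean(vals[[2]])) {
      # identical constant groups: zero difference by convention
      res <- list(statistic = 0, p.value = 1,
                  parameter = sum(ns) - 2)
    } else {
      res <- stats::t.test(vals[[1]], vals[[2]], var.equal = var.equal)
    }
    out <- list(test = "t_test",
                statistic = unname(res$statistic),
                p_value = res$p.value,
                df = unname(res$parameter))
  } else {
    y <- unlist(vals, use.names = FALSE)
    g <- factor(rep(seq_along(vals), ns))
    fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
    out <- list(test = "anova",
                statistic = unname(fit$statistic),
                p_value = fit$p.value,
                df = unname(fit$parameter))
  }
  out$alpha <- alpha
  out$significant <- out$p_value < alpha
  class(out) <- "group_test_result"
  out
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> %s: statistic = %.4g, p = %.4g (alpha = %g) -> %s\n",
              x$test, x$statistic, x$p_value, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
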
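profile_values <- function(p, relative = FALSE) {
  if (inherits(p, "td_profile")) {
    if (relative) p$rel_pct else p$row_means
  } else {
    as.numeric(p)
  }
}

#' Stack top-down profiles of several markers into a matrix
#'
#' Serial sections stained each with a different antibody are colocalized
#' in silico by putting their aligned top-down profiles side by side; rows
#' are positions down the section, columns are markers. Alignment is an
#' upstream responsibility: length mismatches are an error, never silently
#' resampled.
#'
#' @param profiles list of `td_profile` objects (or numeric vectors).
#' @param markers unique marker names, one per profile.
#' @param relative use %-of-max values instead of raw row-mean grey values
#'   (default FALSE; raw GV units keep virtual-knockout fold changes in
#'   grey-value units).
#' @return a `profile_matrix`: numeric matrix `values` (N x M),
#'   `markers`, `positions_um`.
#' @export
stack_profiles <- function(profiles, markers = NULL, relative = FALSE) {
  if (is.null(markers)) {
    markers <- vapply(profiles, function(p) {
      if (inherits(p, "td_profile") && nzchar(p$marker_name)) p$marker_name
      else NA_character_
    }, character(1))
    if (anyNA(markers)) stop("markers must be given when profiles are unnamed",
                             call. = FALSE)
  }
  if (length(markers) != length(profiles)) {
    stop("one marker name per profile required", call. = FALSE)
  }
  if (anyDuplicated(markers)) {
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  }
  lens <- vapply(profiles, function(p) length(profile_values(p)), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("profiles have different lengths (", paste(lens, collapse = ", "),
         "); align serial sections before stacking", call. = FALSE)
  }
  vals <- vapply(profiles, profile_values, numeric(lens[1]),
                 relative = relative)
  colnames(vals) <- markers
  pos <- if (inherits(profiles[[1]], "td_profile")) {
    profiles[[1]]$positions_um
  } else {
    seq_len(lens[1]) - 1
  }
  structure(list(values = vals, markers = markers, positions_um = pos),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d positions x %d markers: %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$markers, collapse = ", ")))
  invisible(x)
}

# shared assembly of a regression_fit from an lm
fit_from_lm <- function(fit, dependent, predictors, n, alpha, ci_level,
                        polynomial_order = 0L) {
  sm <- suppressWarnings(summary(fit))  # self-regression trips the
  # "essentially perfect fit" warning; an R2 of 1 is legitimate here
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  ci <- suppressWarnings(stats::confint(fit, level = ci_level))
  structure(
    list(dependent = dependent,
         predictors = predictors,
         coefficients = stats::coef(fit),
         std_errors = sm$coefficients[, "Std. Error"],
         residual_std_error = sm$sigma,
         R = sqrt(r2),
         R2 = r2,
         F = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
         p = unname(p),
         ci = ci,
         ci_level = ci_level,
         alpha = alpha,
         significant = !is.na(p) && p < alpha,
         predicted = unname(stats::fitted(fit)),
         n = n,
         polynomial_order = polynomial_order,
         lm = fit),
    class = "regression_fit"
  )
}

#' Simple linear regression of one spatial gradient on another
#'
#' Ordinary least squares `y = a + b x` between two equal-length profiles.
#' If two markers colocalize perfectly in space their top-down profiles are
#' linearly related, so R and R^2 measure the amount of spatial overlap.
#' Coefficient confidence intervals are reported at 99% and significance at
#' `alpha = 1e-8`, the conventions used for all gradient correlations here.
#'
#' @param x,y predictor and dependent profiles (`td_profile` or numeric).
#' @param alpha significance level (default `1e-8`).
#' @param ci_level confidence level for coefficient intervals (default 0.99).
#' @param names optional `c(x_name, y_name)` marker labels.
#' @return a `regression_fit`.
#' @export
simple_regression <- function(x, y, alpha = 1e-8, ci_level = 0.99,
                              names = c("x", "y")) {
  xv <- profile_values(x); yv <- profile_values(y)
  if (length(xv) != length(yv)) stop("x and y must have equal length",
                                     call. = FALSE)
  if (length(xv) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(xv) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  out <- fit_from_lm(fit, names[2], names[1], length(xv), alpha, ci_level)
  names(out$coefficients) <- c("(Intercept)", names[1])
  out
}

#' Multiple linear regression of a dependent marker on all others
#'
#' OLS with intercept of one marker's profile on every other marker in the
#' stack, e.g. CD45 (the inflammatory infiltrate) on the HS GAG-related
#' factors. Alongside the joint model, the per-predictor simple-regression
#' R^2 table is reported, which shows which factors drive the fit. Rows
#' where the dependent marker has no data (all-zero in-section count, if
#' supplied) are the caller's responsibility; perfectly collinear predictors
#' are an error.
#'
#' @param X a `profile_matrix`.
#' @param dependent marker name of the dependent variable.
#' @param alpha significance level (default `1e-8`).
#' @param ci_level confidence level for coefficient intervals (default 0.99).
#' @param condition_bound error when the design matrix condition number
#'   (kappa) exceeds this bound (default `1e10`).
#' @return a `regression_fit` with an extra `simple_r2` data.frame.
#' @export
multiple_regression <- function(X, dependent, alpha = 1e-8, ci_level = 0.99,
                                condition_bound = 1e10) {
  stopifnot(inherits(X, "profile_matrix"))
  if (!dependent %in% X$markers) {
    stop("dependent marker '", dependent, "' not in the profile matrix",
         call. = FALSE)
  }
  predictors <- setdiff(X$markers, dependent)
  y <- X$values[, dependent]
  xm <- X$values[, predictors, drop = FALSE]
  n <- nrow(xm)
  if (n <= ncol(xm) + 1L) stop("need more positions than predictors + 1",
                               call. = FALSE)
  design <- cbind(1, xm)
  kappa_val <- kappa(design, exact = TRUE)
  if (kappa_val > condition_bound) {
    cm <- suppressWarnings(stats::cor(xm))
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "predictors are (near-)collinear (condition number %.3g); worst pair: %s / %s",
      kappa_val, predictors[worst[1]], predictors[worst[2]]), call. = FALSE)
  }
  df <- as.data.frame(xm)
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  out <- fit_from_lm(fit, dependent, predictors, n, alpha, ci_level)
  out$simple_r2 <- data.frame(
    predictor = predictors,
    R = vapply(predictors, function(m) {
      f <- simple_regression(xm[, m], y, alpha, ci_level)
      sign(stats::coef(f$lm)[2]) * f$R
    }, numeric(1)),
    R2 = vapply(predictors, function(m)
      simple_regression(xm[, m], y, alpha, ci_level)$R2, numeric(1)),
    row.names = NULL
  )
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  kind <- if (x$polynomial_order > 0)
    sprintf("polynomial refinement (order %d)", x$polynomial_order)
  else if (length(x$predictors) > 1) "multiple linear regression"
  else "simple linear regression"
  cat(sprintf("<regression_fit> %s: %s ~ %s\n", kind, x$dependent,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  R = %.5f, R2 = %.5f, F = %.4g, p = %.3g (alpha = %g) -> %s\n",
              x$R, x$R2, x$F, x$p, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Polynomial refinement of a fitted linear model
#'
#' Refits the relationship between the linear model's predicted profile and
#' the observed dependent profile with a polynomial (6th order by default),
#' a calibration-curve correction that captures a non-linear link while
#' keeping the multiple-regression structure. The refined R^2 can never fall
#' below the linear R^2 because the linear fit is nested in the polynomial.
#'
#' @param fit a `regression_fit` from [simple_regression()] or
#'   [multiple_regression()].
#' @param X the `profile_matrix` used for the fit (to recover the observed
#'   dependent profile); may be omitted, in which case the observed values
#'   are taken from the stored lm.
#' @param order polynomial order >= 1 (default 6).
#' @return a `regression_fit` with `polynomial_order = order`.
#' @export
polynomial_refine <- function(fit, X = NULL, order = 6L) {
  stopifnot(inherits(fit, "regression_fit"))
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  pred <- fit$predicted
  if (order >= length(pred)) stop("order must be < number of points",
                                  call. = FALSE)
  obs <- if (!is.null(X)) X$values[, fit$dependent] else
    pred + stats::resid(fit$lm)
  # orthogonal polynomial basis for numerical stability; fall back to a
  # lower order when the predicted profile has too few distinct values
  ord <- min(order, length(unique(pred)) - 1L)
  if (ord < 1L) {
    # constant prediction: nothing to refine
    pfit <- stats::lm(obs ~ 1)
  } else {
    pfit <- stats::lm(obs ~ poly(pred, ord))
  }
  out <- fit_from_lm(pfit, fit$dependent, fit$predictors, length(obs),
                     fit$alpha, fit$ci_level, polynomial_order = order)
  # guard against round-off pushing the nested comparison the wrong way
  if (out$R2 < fit$R2 - 1e-12 && ord >= 1L) {
    out$R2 <- fit$R2
    out$R <- sqrt(fit$R2)
  }
  out
}

#' Virtual knockout of one predictor
#'
#' Sets the chosen factor's entire top-down profile to zero, recomputes the
#' predicted dependent profile under the already-fitted coefficients, and
#' compares its mean grey value with the baseline prediction. A fold change
#' below 1 means the knockout lowers the predicted dependent signal, i.e.
#' the factor acts "pro" (supporting, e.g. pro-inflammatory when the
#' dependent is CD45); above 1 it acts "anti"; a zero-coefficient factor is
#' neutral. For a linear model the closed form
#' `knockout mean = baseline mean - beta_j * mean(x_j)` holds exactly.
#'
#' @param fit a `regression_fit` from [multiple_regression()] (or
#'   [simple_regression()]).
#' @param X the `profile_matrix` the model was fitted on.
#' @param factor marker name of the predictor to knock out.
#' @param neutral_tol fold changes within this distance of 1 are classed
#'   neutral (default `1e-9`).
#' @return a `vko_result`: `factor`, `baseline_mean_gv`,
#'   `knockout_mean_gv`, `fold_change`, `direction`.
#' @export
virtual_knockout <- function(fit, X, factor, neutral_tol = 1e-9) {
  stopifnot(inherits(fit, "regression_fit"), inherits(X, "profile_matrix"))
  if (!factor %in% fit$predictors) {
    stop("factor '", factor, "' is not a predictor of the fitted model",
         call. = FALSE)
  }
  xm <- X$values[, fit$predictors, drop = FALSE]
  beta <- fit$coefficients
  baseline_pred <- as.numeric(cbind(1, xm) %*% beta)
  xm_ko <- xm
  xm_ko[, factor] <- 0
  ko_pred <- as.numeric(cbind(1, xm_ko) %*% beta)
  baseline <- mean(baseline_pred)
  knockout <- mean(ko_pred)
  if (baseline <= 0) {
    stop("baseline predicted mean GV is not positive; fold change undefined",
         call. = FALSE)
  }
  fold <- knockout / baseline
  direction <- if (abs(fold - 1) <= neutral_tol) "neutral"
  else if (fold < 1) "pro" else "anti"
  structure(
    list(factor = factor,
         baseline_mean_gv = baseline,
         knockout_mean_gv = knockout,
         fold_change = fold,
         direction = direction),
    class = "vko_result"
  )
}

#' @export
print.vko_result <- function(x, ...) {
  cat(sprintf(
    "<vko_result> %s: baseline %.3f -> knockout %.3f GV (fold %.3f, %s)\n",
    x$factor, x$baseline_mean_gv, x$knockout_mean_gv, x$fold_change,
    x$direction))
  invisible(x)
}

#' Virtual knockout of every predictor in turn
#'
#' @inheritParams virtual_knockout
#' @return a data.frame with one row per predictor: `factor`, `baseline`,
#'   `knockout`, `fold`, `direction`.
#' @export
virtual_knockout_all <- function(fit, X, neutral_tol = 1e-9) {
  rows <- lapply(fit$predictors, function(m) {
    v <- virtual_knockout(fit, X, m, neutral_tol)
    data.frame(factor = v$factor, baseline = v$baseline_mean_gv,
               knockout = v$knockout_mean_gv, fold = v$fold_change,
               direction = v$direction)
  })
  do.call(rbind, rows)
}

#' Serial-section compatibility table
#'
#' How many consecutive sections of one sample can be colocalized without
#' significant sampling error? The DAPI profile of a reference section is
#' regressed on the DAPI profile of every `step`-th following section; since
#' DAPI is stained on every section, near-perfect correlation (R^2 close to
#' 1) certifies that shape and cell content are preserved across the stack.
#' The report mirrors the published table layout: R^2, standard error and
#' coefficient in px grey values, 99% CI, F and p, with significance at
#' `alpha = 1e-8`.
#'
#' @param dapi_profiles list of `td_profile` objects, in section order.
#' @param ref_index index of the reference section (default 1).
#' @param step report every `step`-th section after the reference
#'   (default 5); the reference's self-regression is included as the REF
#'   row.
#' @param alpha significance level (default `1e-8`).
#' @return a `serial_compatibility` data.frame: `section`, `R2`,
#'   `std_error`, `coefficient`, `ci_lower`, `ci_upper`, `F`, `p`,
#'   `significant`.
#' @export
serial_compatibility <- function(dapi_profiles, ref_index = 1L, step = 5L,
                                 alpha = 1e-8) {
  n <- length(dapi_profiles)
  if (n < 1L) stop("need at least one profile", call. = FALSE)
  lens <- vapply(dapi_profiles, function(p) length(profile_values(p)),
                 integer(1))
  if (length(unique(lens)) != 1L) {
    stop("profiles have different lengths (", paste(lens, collapse = ", "),
         ")", call. = FALSE)
  }
  y <- profile_values(dapi_profiles[[ref_index]])
  # the reference counts as the 1st section of the sequence, so the stepped
  # sections sit at ref + k*step - 1 (with ref = 1, step = 5: 5, 10, ..., 30)
  stepped <- ref_index + seq_len(n) * step - 1L
  idx <- unique(c(ref_index, stepped[stepped <= n]))
  rows <- lapply(idx, function(i) {
    x <- profile_values(dapi_profiles[[i]])
    fit <- simple_regression(x, y, alpha = alpha)
    slope_row <- 2L
    data.frame(
      section = if (i == ref_index) "REF" else sprintf("%dth", i),
      section_index = i,
      R2 = fit$R2,
      std_error = fit$residual_std_error,
      coefficient = unname(fit$coefficients[slope_row]),
      ci_lower = fit$ci[slope_row, 1],
      ci_upper = fit$ci[slope_row, 2],
      F = fit$F,
      p = fit$p,
      significant = fit$significant
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("serial_compatibility", class(out))
  out
}
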
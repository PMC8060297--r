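make_profiles <- function(n = 200, seed = 61) {
  withr::with_seed(seed, {
    x1 <- pmax(0, 50 + 30 * sin(seq_len(n) / 20) + rnorm(n, 0, 5))
    x2 <- pmax(0, 40 + 25 * cos(seq_len(n) / 15) + rnorm(n, 0, 5))
    x3 <- runif(n, 0, 80)
    y <- pmax(0, 10 + 0.8 * x1 - 0.3 * x2 + rnorm(n, 0, 4))
    list(x1 = x1, x2 = x2, x3 = x3, y = y)
  })
}

test_that("stack_profiles assembles aligned profiles and enforces contracts", {
  p <- make_profiles()
  X <- stack_profiles(p[c("x1", "x2", "y")], c("A", "B", "CD45"))
  expect_identical(dim(X$values), c(200L, 3L))
  expect_identical(X$markers, c("A", "B", "CD45"))
  expect_equal(X$values[, "CD45"], p$y)
  expect_error(stack_profiles(list(p$x1, p$x2[1:100]), c("A", "B")),
               "lengths")
  expect_error(stack_profiles(list(p$x1, p$x2), c("A", "A")), "duplicate")
})

test_that("simple regression reports OLS statistics with 99% CIs", {
  p <- make_profiles()
  self <- simple_regression(p$y, p$y)
  expect_equal(self$R2, 1)
  expect_equal(unname(self$coefficients[2]), 1)
  fit <- simple_regression(p$x1, p$y)
  # R2 equals squared Pearson correlation
  expect_equal(fit$R2, cor(p$x1, p$y)^2, tolerance = 1e-10)
  expect_equal(fit$R, abs(cor(p$x1, p$y)), tolerance = 1e-10)
  # slope inside its own 99% CI
  expect_true(fit$ci[2, 1] <= fit$coefficients[2] &&
                fit$coefficients[2] <= fit$ci[2, 2])
  expect_error(simple_regression(rep(1, 10), rnorm(10)), "variance")
  # independent noise at profile length 8800 explains essentially nothing
  withr::with_seed(62, {
    xa <- rnorm(8800); yb <- rnorm(8800)
  })
  expect_lt(simple_regression(xa, yb)$R2, 0.05)
})

test_that("slope recovery: 99% CI covers the true slope in most replicates", {
  hits <- 0L
  for (r in 1:200) {
    withr::with_seed(1000L + r, {
      x <- runif(60, 0, 100)
      y <- 2 * x + rnorm(60, 0, 10)
    })
    fit <- simple_regression(x, y)
    if (fit$ci[2, 1] <= 2 && 2 <= fit$ci[2, 2]) hits <- hits + 1L
  }
  expect_gte(hits, 190L)   # nominal 99%; 190/200 leaves generous slack
})

test_that("multiple regression nests simple regression and is monotone in R2", {
  p <- make_profiles()
  X1 <- stack_profiles(p[c("x1", "y")], c("A", "CD45"))
  multi1 <- multiple_regression(X1, "CD45")
  lone <- simple_regression(p$x1, p$y)
  expect_equal(multi1$R2, lone$R2, tolerance = 1e-12)
  expect_equal(unname(multi1$coefficients), unname(lone$coefficients),
               tolerance = 1e-10)
  X3 <- stack_profiles(p[c("x1", "x2", "x3", "y")], c("A", "B", "N", "CD45"))
  multi3 <- multiple_regression(X3, "CD45")
  # adding predictors (even pure noise) never lowers R2
  X2 <- stack_profiles(p[c("x1", "x2", "y")], c("A", "B", "CD45"))
  multi2 <- multiple_regression(X2, "CD45")
  expect_gte(multi3$R2, multi2$R2)
  expect_gte(multi2$R2, lone$R2)
  expect_gte(multi2$R2, max(multi2$simple_r2$R2))
  # collinear predictors are refused by name
  pc <- p; pc$x2 <- 2 * pc$x1
  Xc <- stack_profiles(pc[c("x1", "x2", "y")], c("A", "B", "CD45"))
  expect_error(multiple_regression(Xc, "CD45"), "collinear")
  expect_error(multiple_regression(X2, "nope"), "not in the profile")
})

test_that("multiple regression recovers known coefficients within 99% CIs", {
  beta <- c(A = 1.5, B = -0.8, C = 0.4)
  withr::with_seed(63, {
    xm <- matrix(runif(3 * 500, 0, 100), 500, 3)
    y <- 20 + xm %*% beta + rnorm(500, 0, 10)
  })
  X <- stack_profiles(list(xm[, 1], xm[, 2], xm[, 3], as.numeric(y)),
                      c("A", "B", "C", "CD45"))
  fit <- multiple_regression(X, "CD45")
  for (k in 1:3) {
    expect_true(fit$ci[k + 1, 1] <= beta[k] && beta[k] <= fit$ci[k + 1, 2])
  }
})

test_that("coefficient recovery stays accurate over 50 seeded simulations", {
  # N = 2000, noise sd 10 GV, known slopes: median relative error < 5%
  beta <- c(1.2, -0.6)
  errs <- matrix(NA_real_, 50, 2)
  for (r in 1:50) {
    withr::with_seed(2000L + r, {
      xm <- matrix(runif(2 * 2000, 0, 100), 2000, 2)
      y <- 15 + xm %*% beta + rnorm(2000, 0, 10)
    })
    X <- stack_profiles(list(xm[, 1], xm[, 2], as.numeric(y)),
                        c("A", "B", "CD45"))
    fit <- multiple_regression(X, "CD45")
    errs[r, ] <- abs(unname(fit$coefficients[2:3]) - beta) / abs(beta)
  }
  expect_lt(median(errs), 0.05)
})

test_that("polynomial refinement behaves as a nested calibration curve", {
  p <- make_profiles()
  X <- stack_profiles(p[c("x1", "x2", "y")], c("A", "B", "CD45"))
  fit <- multiple_regression(X, "CD45")
  # order 1 reproduces the linear fit's R2
  expect_equal(polynomial_refine(fit, X, order = 1)$R2, fit$R2,
               tolerance = 1e-10)
  ref6 <- polynomial_refine(fit, X)
  expect_identical(ref6$polynomial_order, 6L)
  expect_gte(ref6$R2, fit$R2)
  # perfectly linear data stay at R2 = 1
  lin <- simple_regression(p$x1, 3 * p$x1 + 2)
  expect_equal(polynomial_refine(lin, order = 6)$R2, 1)
  # a saturating link leaves room the polynomial can pick up
  withr::with_seed(64, {
    x <- runif(400, 0, 100)
    y <- 200 / (1 + exp(-(x - 50) / 10)) + rnorm(400, 0, 3)
  })
  sfit <- simple_regression(x, y)
  sref <- polynomial_refine(sfit, order = 6)
  expect_gt(sref$R2, sfit$R2 + 0.01)
  expect_error(polynomial_refine(sfit, order = 400), "order")
})

test_that("virtual knockout matches its closed form for every fitted model", {
  for (r in 1:20) {
    withr::with_seed(3000L + r, {
      xm <- matrix(runif(3 * 150, 0, 100), 150, 3)
      y <- 50 + xm %*% runif(3, -0.2, 1.5) + rnorm(150, 0, 8)
    })
    X <- stack_profiles(list(xm[, 1], xm[, 2], xm[, 3], as.numeric(y)),
                        c("A", "B", "C", "CD45"))
    fit <- multiple_regression(X, "CD45")
    for (m in c("A", "B", "C")) {
      v <- virtual_knockout(fit, X, m)
      # closed form: knockout mean = baseline mean - beta_j * mean(x_j)
      analytic <- v$baseline_mean_gv -
        unname(fit$coefficients[m]) * mean(xm[, match(m, c("A", "B", "C"))])
      expect_equal(v$knockout_mean_gv, analytic, tolerance = 1e-8)
    }
  }
})

test_that("virtual knockout classifies directions from the fold change", {
  withr::with_seed(65, {
    x1 <- runif(300, 10, 100)
    x2 <- runif(300, 10, 100)
    y <- 5 + 2 * x1 + 0 * x2 + rnorm(300, 0, 1)
  })
  X <- stack_profiles(list(x1, x2, y), c("UP", "NIL", "CD45"))
  fit <- multiple_regression(X, "CD45")
  up <- virtual_knockout(fit, X, "UP")
  expect_lt(up$fold_change, 1)       # large positive effect: pro
  expect_identical(up$direction, "pro")
  # force a coefficient of exactly zero: neutral with fold change 1
  fit0 <- fit
  fit0$coefficients["NIL"] <- 0
  nil <- virtual_knockout(fit0, X, "NIL")
  expect_equal(nil$fold_change, 1)
  expect_identical(nil$direction, "neutral")
  expect_error(virtual_knockout(fit, X, "GONE"), "not a predictor")
  tab <- virtual_knockout_all(fit, X)
  expect_identical(tab$factor, c("UP", "NIL"))
})

test_that("serial compatibility reports the table layout and trivial rows", {
  p <- make_profiles()
  same <- lapply(1:11, function(i) p$y)
  tab <- serial_compatibility(same, ref_index = 1, step = 5)
  expect_identical(tab$section, c("REF", "5th", "10th"))
  expect_true(all(tab$R2 == 1))
  expect_equal(tab$coefficient, rep(1, 3))
  # all rows significant at alpha 1e-8 for strongly correlated profiles
  withr::with_seed(66, {
    drift <- lapply(1:11, function(i) p$y + rnorm(200, 0, i / 2))
  })
  tab2 <- serial_compatibility(drift, 1, 5)
  expect_true(all(tab2$significant))
  expect_true(all(tab2$p < 1e-8))
  expect_error(serial_compatibility(list(p$y, p$y[1:10])), "lengths")
})
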
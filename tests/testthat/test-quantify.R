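test_that("gv_histogram always reports 256 bins and matches the tally oracle", {
  a <- random_grey(64, 64, seed = 41)
  h <- gv_histogram(a, full_mask(64, 64))
  expect_identical(length(h$abs_counts), 256L)
  expect_identical(sum(h$abs_counts), 64L * 64L)  # conservation
  # independent oracle: per-pixel tally
  oracle <- integer(256)
  for (v in as.vector(a$pixels)) oracle[v + 1L] <- oracle[v + 1L] + 1L
  expect_identical(h$abs_counts, oracle)
  expect_equal(sum(h$rel_counts_pct), 100)
  # uniform in-mask value concentrates one bin
  u <- grey_image(matrix(42L, 10, 10))
  hu <- gv_histogram(u, full_mask(10, 10))
  expect_identical(hu$abs_counts[43L], 100L)
  expect_identical(sum(hu$abs_counts[-43L]), 0L)
  expect_error(gv_histogram(a, binary_mask(matrix(0L, 64, 64))), "empty")
})

test_that("histogram masking uses only in-mask pixels with mask-area denominator", {
  a <- random_grey(32, 32, seed = 42)
  m <- binarize(random_grey(32, 32, seed = 43), 128)
  h <- gv_histogram(a, m)
  expect_identical(sum(h$abs_counts), sum(m$pixels == 255L))
  expect_identical(h$reference_area_px, sum(m$pixels == 255L))
  expect_equal(h$rel_counts_pct, 100 * h$abs_counts / h$reference_area_px)
})

test_that("truncation at t leaves 256 - t bins and preserves the domain sum", {
  a <- random_grey(64, 64, seed = 44)
  h <- gv_histogram(a, full_mask(64, 64))
  t10 <- truncate_histogram(h, 10)
  expect_identical(length(t10$gv), 246L)
  expect_identical(t10$threshold, 10L)
  expect_identical(length(truncate_histogram(h, 0)$gv), 256L)
  expect_equal(sum(t10$rel_counts_pct), expression_domain(h, 10))
  expect_equal(expression_domain(t10), expression_domain(h, 10))
  expect_error(truncate_histogram(h, 300))
})

test_that("expression domain matches the counting oracle and is monotone in t", {
  a <- random_grey(48, 48, seed = 45)
  h <- gv_histogram(a, full_mask(48, 48))
  for (t in c(0L, 10L, 97L, 255L)) {
    n <- 0L
    for (v in as.vector(a$pixels)) if (v >= t) n <- n + 1L
    expect_equal(expression_domain(h, t), 100 * n / (48 * 48))
  }
  doms <- vapply(0:255, function(t) expression_domain(h, t), numeric(1))
  expect_true(all(diff(doms) <= 0))
  expect_equal(doms[1], 100)
})

test_that("td_profile computes background-excluded row means and calibration", {
  # in-section {100, 200} plus background {0, 0}: row mean 150, not 75
  px <- matrix(c(100L, 200L, 0L, 0L), 1, 4)
  m <- binary_mask(matrix(c(255L, 255L, 0L, 0L), 1, 4), role = "section")
  img <- grey_image(rbind(px, px))
  msk <- binary_mask(rbind(m$pixels, m$pixels), role = "section")
  p <- td_profile(img, msk)
  expect_equal(p$row_means, c(150, 150))
  expect_identical(p$in_section_counts, c(2L, 2L))
  # calibration: 8800 rows at 0.53937 um/px span 4745.9 um
  tall <- grey_image(matrix(0L, 8800, 2), resolution_um_per_px = 0.53937)
  pt <- td_profile(tall, full_mask(8800, 2))
  expect_equal(round(pt$total_distance_um, 1), 4745.9)
  expect_identical(length(pt$row_means), 8800L)
  expect_equal(pt$positions_um[1], 0)
  expect_true(all(diff(pt$positions_um) > 0))
  # constant in-mask value: flat profile at 100% relative
  cimg <- grey_image(matrix(37L, 20, 10))
  cp <- td_profile(cimg, full_mask(20, 10))
  expect_true(all(cp$row_means == 37))
  expect_true(all(cp$rel_pct == 100))
  expect_error(td_profile(cimg, binary_mask(matrix(0L, 20, 10))), "empty")
})

test_that("td_profile matches a loop oracle and flips with the image", {
  a <- random_grey(40, 30, seed = 46)
  m <- binarize(random_grey(40, 30, seed = 47), 100)
  m$role <- "section"
  p <- td_profile(a, m)
  for (i in seq(1, 40, by = 3)) {
    sel <- m$pixels[i, ] == 255L
    expected <- if (any(sel)) mean(a$pixels[i, sel]) else 0
    expect_equal(p$row_means[i], expected)
  }
  expect_equal(max(p$rel_pct), 100)
  flip <- function(x) x[rev(seq_len(nrow(x))), , drop = FALSE]
  pf <- td_profile(grey_image(flip(a$pixels)),
                   binary_mask(flip(m$pixels), role = "section"))
  expect_equal(pf$row_means, rev(p$row_means))
})

test_that("compare_groups runs the stated t-test and ANOVA conventions", {
  g1 <- c(9.2, 10.1, 11.3, 9.8)
  res <- compare_groups(list(a = g1, b = g1), test = "t_test")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_equal(res$alpha, 0.1)
  # two-group ANOVA F equals t^2 from the pooled t-test
  withr::with_seed(48, {
    x <- rnorm(12, 10, 2); y <- rnorm(15, 12, 2)
  })
  tt <- compare_groups(list(x, y), test = "t_test")
  an <- compare_groups(list(x, y), test = "anova")
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$alpha, 0.01)
  expect_error(compare_groups(list(x)), "2 groups")
  expect_error(compare_groups(list(x, 1), test = "t_test"), "2 observations")
})

test_that("an injected domain shift is detected by the histogram ANOVA", {
  # two groups of synthetic sections whose configured marker domains differ
  make_hist <- function(domain, seed) {
    p <- small_params(markers = list(marker_config("M", domain_pct = domain)))
    s <- generate_section(p, seed)
    truncate_histogram(
      gv_histogram(s$markers$M, s$truth$geometry$section_mask), 10)
  }
  healthy <- lapply(1:3, function(i) make_hist(20, i))
  diseased <- lapply(1:3, function(i) make_hist(45, 100 + i))
  res <- compare_groups(list(healthy, diseased), test = "anova")
  expect_true(res$significant)
  expect_lt(res$p_value, 0.01)
})
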
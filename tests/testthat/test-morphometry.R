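test_that("closing bridges gaps and hole filling whitens enclosed voids", {
  # ring with a 3-px gap and an enclosed hole
  m <- matrix(0L, 40, 40)
  m[10:30, 10:30] <- 255L
  m[15:25, 15:25] <- 0L        # enclosed hole
  ring <- binary_mask(m, role = "section")
  filled <- fill_holes(ring)
  expect_identical(sum(filled$pixels == 255L), 21L * 21L)
  # an isolated point survives closing unchanged
  pt <- matrix(0L, 21, 21); pt[11, 11] <- 255L
  expect_identical(mask_close(binary_mask(pt), 5)$pixels, pt)
  # two squares 6 px apart merge under closing radius 4 (disk diameter 8)
  two <- matrix(0L, 30, 40)
  two[10:20, 5:15] <- 255L
  two[10:20, 22:32] <- 255L
  closed <- mask_close(binary_mask(two), 4)
  mid <- closed$pixels[15, 16:21]
  expect_true(all(mid == 255L))
  # erosion then dilation never grows a mask
  a <- binarize(random_grey(40, 40, seed = 2), 128)
  opened <- mask_dilate(mask_erode(a, 2), 2)
  expect_true(all(opened$pixels <= a$pixels))
})

test_that("build_section_mask recovers the synthetic ground-truth footprint", {
  s <- generate_section(small_params(), seed = 4)
  truth <- s$truth$geometry$section_mask$pixels == 255L
  # closing radius scaled to the small test canvas (15 px is the
  # full-panorama default and overfills boundary concavities at this size)
  m <- build_section_mask(s$markers$Sdc1, s$dapi,
                          close_radius_px = 8L)$pixels == 255L
  iou <- sum(truth & m) / sum(truth | m)
  # boundary uncertainty is a 1-2 px band around a ~100 px-radius blob
  expect_gt(iou, 0.95)
  # empty input contract
  z <- grey_image(matrix(0L, 20, 20))
  expect_warning(em <- build_section_mask(z, z), "empty")
  expect_true(all(em$pixels == 0L))
  # disjoint marker-only and DAPI-only regions both enter the merge
  a <- matrix(0L, 30, 30); a[5:8, 5:8] <- 200L
  b <- matrix(0L, 30, 30); b[20:23, 20:23] <- 150L
  merged <- binarize(blend_lighten(grey_image(a), grey_image(b)), 1)
  expect_identical(sum(merged$pixels == 255L), 32L)
})

test_that("adding signal pixels never shrinks the section mask", {
  s <- generate_section(small_params(), seed = 6)
  base <- build_section_mask(s$markers$Sdc1, s$dapi, close_radius_px = 8L)
  more <- s$markers$Sdc1$pixels
  withr::with_seed(8, {
    idx <- sample(length(more), 500)
    more[idx] <- pmax(more[idx], 200L)
  })
  grown <- build_section_mask(grey_image(more), s$dapi, close_radius_px = 8L)
  expect_true(all(grown$pixels >= base$pixels))
})

test_that("split_compartments partitions the section exactly", {
  s <- generate_section(small_params(), seed = 5)
  g <- s$truth$geometry
  sec <- g$section_mask$pixels; epi <- g$epithelial_mask$pixels
  str <- g$stromal_mask$pixels
  # per-pixel set-arithmetic oracle
  for (i in seq(1, nrow(sec), by = 7)) {
    for (j in seq(1, ncol(sec), by = 7)) {
      expect_identical(str[i, j],
                       if (sec[i, j] == 255L && epi[i, j] == 0L) 255L else 0L)
    }
  }
  expect_identical(sum(epi == 255L) + sum(str == 255L), sum(sec == 255L))
  expect_true(all(epi == 0L | str == 0L))
  # degenerate splits
  full <- binary_mask(sec, role = "section")
  g2 <- split_compartments(full, binary_mask(sec, role = "epithelial"))
  expect_identical(sum(g2$stromal_mask$pixels == 255L), 0L)
  g3 <- split_compartments(full, binary_mask(matrix(0L, nrow(sec), ncol(sec)),
                                             role = "epithelial"))
  expect_identical(g3$stromal_mask$pixels, sec)
  # epithelial pixels outside the section are cleared with a warning
  out_epi <- matrix(0L, nrow(sec), ncol(sec))
  out_epi[sec == 0L][1:10] <- 255L
  expect_warning(split_compartments(full, binary_mask(out_epi, role = "epithelial")),
                 "cleared")
})

test_that("measure_areas converts px to mm2 and reports exact fractions", {
  sec <- matrix(255L, 100, 100)
  epi <- matrix(0L, 100, 100); epi[seq_len(1842)] <- 255L
  g <- split_compartments(binary_mask(sec, role = "section"),
                          binary_mask(epi, role = "epithelial"),
                          resolution_um_per_px = 0.53937)
  ar <- measure_areas(g)
  expect_identical(ar$whole_px, 10000L)
  expect_equal(ar$whole_mm2, 10000 * (0.53937e-3)^2, tolerance = 1e-12)
  expect_equal(ar$whole_mm2, 0.0029092, tolerance = 1e-4)
  # the 1842:8158 px split prints as 18.42% / 81.58%
  expect_equal(ar$epi_pct, 18.42)
  expect_equal(ar$stroma_pct, 81.58)
  expect_equal(ar$epi_pct + ar$stroma_pct, 100)
  # mm2 scales quadratically with resolution
  g2 <- g; g2$resolution_um_per_px <- 2 * 0.53937
  expect_equal(measure_areas(g2)$whole_mm2, 4 * ar$whole_mm2)
  # zero-area error
  g0 <- g; g0$section_mask <- binary_mask(matrix(0L, 100, 100), role = "section")
  expect_error(measure_areas(g0), "empty")
})

test_that("cellularity counts supra-threshold DAPI inside the mask only", {
  px <- matrix(0L, 40, 25)
  px[1:260] <- 10L                  # 260 of 1000 px at GV >= 10
  dapi <- grey_image(px)
  expect_equal(cellularity(dapi, full_mask(40, 25)), 26.0)
  expect_equal(cellularity(grey_image(matrix(0L, 10, 10)), full_mask(10, 10)), 0)
  # loop oracle on a random image
  d <- random_grey(32, 32, seed = 31)
  m <- binarize(random_grey(32, 32, seed = 32), 120)
  ok <- tot <- 0L
  for (i in 1:32) for (j in 1:32) {
    if (m$pixels[i, j] == 255L) {
      tot <- tot + 1L
      if (d$pixels[i, j] >= 10L) ok <- ok + 1L
    }
  }
  expect_equal(cellularity(d, m), 100 * ok / tot)
  # perturbing out-of-mask pixels changes nothing
  d2 <- d$pixels
  d2[m$pixels == 0L] <- 255L
  expect_equal(cellularity(grey_image(d2), m), cellularity(d, m))
  expect_error(cellularity(d, binary_mask(matrix(0L, 32, 32))), "empty")
})
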
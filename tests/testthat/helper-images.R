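# fixtures are built in code; images are small and seeded

random_grey <- function(h = 64L, w = 64L, seed = 1L, max_gv = 255L) {
  withr::with_seed(seed, {
    grey_image(matrix(sample(0:max_gv, h * w, replace = TRUE), h, w))
  })
}

full_mask <- function(h, w, role = "section") {
  binary_mask(matrix(255L, h, w), role = role)
}

# small canvas shared by the synthetic-pipeline tests
small_params <- function(...) {
  section_params(height = 320L, width = 200L, ...)
}
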
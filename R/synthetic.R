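#' Marker configuration for the synthetic generator
#'
#' Describes one IF marker channel of a synthetic section: how much of the
#' section its supra-threshold signal covers, how strongly it prefers the
#' epithelial compartment, and whether it shares the inflammatory-infiltrate
#' hotspot.
#'
#' @param name marker label.
#' @param domain_pct target expression domain as % of section area.
#' @param epithelial_bias multiplicative weight of the smooth field inside
#'   the epithelial rim (1 = no compartment preference; > 1 epithelial,
#'   < 1 stromal).
#' @param hotspot_amp amplitude of the shared stromal hotspot added to the
#'   marker's intensity field (0 disables it).
#' @param floor_gv autofluorescence floor: signal pixels are rendered at
#'   grey values `>= floor_gv`, everything else stays below it.
#' @return a list of class `marker_config`.
#' @export
marker_config <- function(name, domain_pct = 30, epithelial_bias = 1,
                          hotspot_amp = 0, floor_gv = 10L) {
  if (domain_pct < 0 || domain_pct > 100) {
    stop("domain_pct must be in [0, 100]", call. = FALSE)
  }
  if (floor_gv < 1 || floor_gv > 254) stop("floor_gv must be in 1..254",
                                           call. = FALSE)
  structure(list(name = name, domain_pct = domain_pct,
                 epithelial_bias = epithelial_bias,
                 hotspot_amp = hotspot_amp,
                 floor_gv = as.integer(floor_gv)),
            class = "marker_config")
}

#' Default parameters of a synthetic gingiva-like panorama
#'
#' The stated world of the test images: a desk-scale 1600 x 1024 px canvas
#' (stand-in for ~12000 x 6000 px panoramas) at the 10x scan resolution of
#' 0.53937 um/px; an epithelial rim holding 25% of the section; DAPI
#' cellularity of 26% (a healthy-gingiva-like value); an autofluorescence
#' floor at grey value 10; and a marker panel in which CD45 marks a stromal
#' inflammatory hotspot shared (with varying amplitude) by part of the HS
#' GAG-related factors.
#'
#' @param height,width canvas size in px.
#' @param resolution_um_per_px pixel size in micrometres.
#' @param epithelial_fraction_pct epithelial rim area as % of section area.
#' @param cellularity_pct DAPI expression domain as % of section area.
#' @param floor_gv autofluorescence floor grey value.
#' @param noise_sd grey-value noise added to signal pixels (clamped so the
#'   configured domains stay exact).
#' @param markers list of [marker_config()] objects.
#' @param sample_id sample label stamped on the images.
#' @return a named parameter list.
#' @export
section_params <- function(height = 1600L, width = 1024L,
                           resolution_um_per_px = 0.53937,
                           epithelial_fraction_pct = 25,
                           cellularity_pct = 26,
                           floor_gv = 10L,
                           noise_sd = 2,
                           markers = default_marker_panel(floor_gv),
                           sample_id = "SYN-01") {
  if (epithelial_fraction_pct < 0 || epithelial_fraction_pct > 100) {
    stop("epithelial_fraction_pct must be in [0, 100]", call. = FALSE)
  }
  if (cellularity_pct < 0 || cellularity_pct > 100) {
    stop("cellularity_pct must be in [0, 100]", call. = FALSE)
  }
  list(height = as.integer(height), width = as.integer(width),
       resolution_um_per_px = resolution_um_per_px,
       epithelial_fraction_pct = epithelial_fraction_pct,
       cellularity_pct = cellularity_pct,
       floor_gv = as.integer(floor_gv),
       noise_sd = noise_sd,
       markers = markers,
       sample_id = sample_id)
}

#' @rdname section_params
#' @export
default_marker_panel <- function(floor_gv = 10L) {
  list(
    marker_config("CD45",  domain_pct = 20, epithelial_bias = 0.3,
                  hotspot_amp = 1.0, floor_gv = floor_gv),
    marker_config("Sdc1",  domain_pct = 30, epithelial_bias = 3.0,
                  hotspot_amp = 0,   floor_gv = floor_gv),
    marker_config("EXT1",  domain_pct = 25, epithelial_bias = 0.6,
                  hotspot_amp = 0.8, floor_gv = floor_gv),
    marker_config("EXT2",  domain_pct = 40, epithelial_bias = 1.0,
                  hotspot_amp = 0,   floor_gv = floor_gv),
    marker_config("NDST1", domain_pct = 35, epithelial_bias = 1.0,
                  hotspot_amp = 0.1, floor_gv = floor_gv),
    marker_config("NDST2", domain_pct = 25, epithelial_bias = 0.5,
                  hotspot_amp = 0.9, floor_gv = floor_gv)
  )
}

# separable gaussian blur by shifted accumulation, kernel renormalized at
# the borders so flat fields stay flat
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv_rows <- function(x) {
    n <- nrow(x)
    acc <- matrix(0, n, ncol(x))
    wsum <- matrix(0, n, ncol(x))
    for (o in -half:half) {
      src <- max(1L, 1L - o):min(n, n - o)
      dst <- src + o
      wk <- k[o + half + 1L]
      acc[dst, ] <- acc[dst, ] + wk * x[src, ]
      wsum[dst, ] <- wsum[dst, ] + wk
    }
    acc / wsum
  }
  t(conv_rows(t(conv_rows(m))))
}

# bilinear upsampling of a coarse field to h x w
bilinear_upsample <- function(m, h, w) {
  src_y <- seq(1, nrow(m), length.out = h)
  src_x <- seq(1, ncol(m), length.out = w)
  y0 <- pmin(floor(src_y), nrow(m) - 1L); fy <- src_y - y0
  x0 <- pmin(floor(src_x), ncol(m) - 1L); fx <- src_x - x0
  a <- m[y0, x0, drop = FALSE];     b <- m[y0 + 1L, x0, drop = FALSE]
  c_ <- m[y0, x0 + 1L, drop = FALSE]; d <- m[y0 + 1L, x0 + 1L, drop = FALSE]
  fy_m <- matrix(fy, h, w); fx_m <- matrix(fx, h, w, byrow = TRUE)
  a * (1 - fy_m) * (1 - fx_m) + b * fy_m * (1 - fx_m) +
    c_ * (1 - fy_m) * fx_m + d * fy_m * fx_m
}

# seeded low-frequency random field: white noise blurred at sigma/factor on
# a coarse grid, then bilinearly upsampled (much cheaper than full-scale
# blur, indistinguishable for the smooth fields the generator needs)
smooth_field <- function(h, w, sigma, factor = 8L) {
  ch <- max(8L, ceiling(h / factor)); cw <- max(8L, ceiling(w / factor))
  coarse <- gaussian_blur(matrix(stats::rnorm(ch * cw), ch, cw),
                          sigma / factor)
  bilinear_upsample(coarse, h, w)
}

# smooth periodic boundary-perturbation function of the polar angle
boundary_harmonics <- function(coefs, theta) {
  out <- rep(0, length(theta))
  for (k in seq_len(nrow(coefs))) {
    out <- out + coefs[k, 1] * cos((k + 1) * theta) +
                 coefs[k, 2] * sin((k + 1) * theta)
  }
  out
}

draw_boundary_coefs <- function(n_harmonics = 5L, sd0 = 0.07) {
  cbind(stats::rnorm(n_harmonics, 0, sd0 / seq_len(n_harmonics)),
        stats::rnorm(n_harmonics, 0, sd0 / seq_len(n_harmonics)))
}

# rasterize the blob: TRUE inside the perturbed ellipse
rasterize_blob <- function(height, width, center, semi_axes, coefs) {
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  dy <- (yy - center[1]) / semi_axes[1]
  dx <- (xx - center[2]) / semi_axes[2]
  theta <- atan2(dy, dx)
  r <- sqrt(dy^2 + dx^2)
  r <= 1 + boundary_harmonics(coefs, theta)
}

# map an intensity field to 8-bit marker grey values with an exact domain:
# the top `domain_pct`% of in-section pixels are linearly rescaled to
# [floor, 255], the rest become sub-floor autofluorescence
render_marker <- function(field, inside, domain_pct, floor_gv, noise_sd,
                          background_noise) {
  px <- background_noise              # starts as sub-floor noise everywhere
  vals <- field[inside]
  if (domain_pct > 0 && length(vals) > 0) {
    q <- stats::quantile(vals, probs = 1 - domain_pct / 100, names = FALSE,
                         type = 7)
    sel <- inside & field > q
    if (any(sel)) {
      v <- field[sel]
      span <- max(v) - q
      scaled <- if (span > 0) (v - q) / span else rep(1, length(v))
      # cube the normalized intensity: IF grey-value histograms decay
      # steeply from the floor, with strong signal rare
      gv <- floor_gv + scaled^3 * (255 - floor_gv)
      if (noise_sd > 0) gv <- gv + stats::rnorm(length(gv), 0, noise_sd)
      px[sel] <- as.integer(pmin(255, pmax(floor_gv, round_half_up(gv))))
    }
  }
  px
}

#' Generate one synthetic panoramic section with ground truth
#'
#' Builds a blob-shaped tissue section on a dark background, an epithelial
#' rim of configured area fraction (the in-section pixels nearest the
#' boundary), a DAPI nuclei speckle hitting the configured cellularity, and
#' one marker channel per [marker_config()]: autofluorescence below the
#' floor grey value everywhere, plus a compartment-weighted smooth signal
#' field and an optional shared stromal hotspot rendered at grey values
#' `floor..255` over exactly the configured domain fraction. Everything is
#' deterministic per seed.
#'
#' @param params a [section_params()] list.
#' @param seed integer RNG seed.
#' @return a `synthetic_sample`: `dapi` (`grey_image`), `markers` (named
#'   list of `grey_image`), `background_mask`, `truth` (geometry, configured
#'   domains, floor, cellularity, hotspot center), `seed`, `params`.
#' @export
generate_section <- function(params = section_params(), seed = 1L) {
  withr::with_seed(as.integer(seed), generate_section_impl(params, seed))
}

generate_section_impl <- function(params, seed, state = NULL) {
  h <- params$height; w <- params$width
  floor_gv <- params$floor_gv
  if (floor_gv >= 255) stop("floor_gv must leave room for signal",
                            call. = FALSE)

  # --- section footprint ----------------------------------------------
  # `state` (used by the serial-stack generator) pins the shape and the
  # random fields; standalone sections draw everything fresh
  if (is.null(state)) state <- list()
  center <- state$center %||% c(h, w) / 2
  semi_axes <- state$semi_axes %||% c(0.40 * h, 0.38 * w)
  coefs <- state$coefs %||% draw_boundary_coefs()
  inside <- rasterize_blob(h, w, center, semi_axes, coefs)
  if (!any(inside)) stop("degenerate parameters: empty section", call. = FALSE)
  section_px <- matrix(0L, h, w); section_px[inside] <- 255L
  section_mask <- binary_mask(section_px, role = "section")
  background_mask <- invert_mask(section_mask)
  background_mask$role <- "background"

  # --- epithelial rim: in-section pixels nearest the boundary ----------
  d2 <- .cpp_edt_sq(!inside)               # squared distance to background
  din <- sqrt(d2[inside])
  frac <- params$epithelial_fraction_pct / 100
  epi <- matrix(0L, h, w)
  if (frac > 0) {
    cut <- stats::quantile(din, probs = frac, names = FALSE, type = 1)
    epi[inside & sqrt(d2) <= cut] <- 255L
  }
  geometry <- suppressWarnings(
    split_compartments(section_mask, binary_mask(epi, role = "epithelial"),
                       params$resolution_um_per_px))

  # --- shared sub-floor texture ---------------------------------------
  # autofluorescence is a tissue property: inside the section, non-signal
  # pixels carry dense faint speckle at GV 1..floor-1; the camera background
  # outside is near-black with only rare hot pixels (sparse enough that the
  # closing step of mask construction cannot glue it into the section)
  bg_noise <- function(af_density = 0.3, bg_density = 5e-4) {
    px <- matrix(0L, h, w)
    af <- inside & stats::runif(h * w) < af_density
    bg <- !inside & stats::runif(h * w) < bg_density
    n_sub <- sum(af) + sum(bg)
    px[af | bg] <- as.integer(stats::runif(n_sub, 1, floor_gv - 1e-9))
    # a few debris particles at floor-1 pin the stated autofluorescence
    # floor exactly, even on small canvases where the sparse speckle might
    # otherwise top out below it
    out_idx <- which(!inside)
    if (length(out_idx) >= 8L && floor_gv > 1L) {
      px[sample(out_idx, 8L)] <- floor_gv - 1L
    }
    px
  }

  # --- DAPI speckle -----------------------------------------------------
  nuc_field <- state$nuc_field %||%
    gaussian_blur(matrix(stats::rnorm(h * w), h, w), 1.5)
  dapi_px <- bg_noise()
  cfrac <- params$cellularity_pct / 100
  if (cfrac > 0) {
    qn <- stats::quantile(nuc_field[inside], probs = 1 - cfrac, names = FALSE)
    nuc <- inside & nuc_field > qn
    # nuclei brightness is a deterministic map of the speckle field, so
    # consecutive serial sections differ only through the field drift
    v <- nuc_field[nuc]
    span <- max(v) - qn
    scaled <- if (span > 0) (v - qn) / span else rep(1, length(v))
    dapi_px[nuc] <- as.integer(round_half_up(60 + scaled * 195))
  }
  dapi <- grey_image(dapi_px, params$resolution_um_per_px, channel = "dapi",
                     marker_name = "DAPI", sample_id = params$sample_id)

  # --- inflammatory hotspot shared by part of the marker panel ---------
  hot_center <- center + c(0.45, 0.25) * semi_axes  # stromal, off-centre
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  hot_sigma <- 0.22 * min(semi_axes)
  hotspot <- exp(-((yy - hot_center[1])^2 + (xx - hot_center[2])^2) /
                   (2 * hot_sigma^2))

  epi_w <- geometry$epithelial_mask$pixels == 255L
  markers <- list()
  domains <- numeric(0)
  marker_fields <- list()
  for (cfg in params$markers) {
    smooth <- state$marker_fields[[cfg$name]] %||% smooth_field(h, w, 40)
    marker_fields[[cfg$name]] <- smooth
    smooth <- (smooth - min(smooth)) / (max(smooth) - min(smooth))
    # real IF staining is fine-grained (fibres, membranes), not a smooth
    # ramp: a high-frequency component gives weak signal its on/off speckle
    fine <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), 2)
    fine <- (fine - min(fine)) / (max(fine) - min(fine))
    weight <- ifelse(epi_w, cfg$epithelial_bias, 1)
    field <- (0.6 * smooth + 0.4 * fine) * weight + cfg$hotspot_amp * hotspot
    px <- render_marker(field, inside, cfg$domain_pct, cfg$floor_gv,
                        params$noise_sd, bg_noise())
    markers[[cfg$name]] <- grey_image(
      px, params$resolution_um_per_px, channel = "marker",
      marker_name = cfg$name, sample_id = params$sample_id)
    domains[cfg$name] <- cfg$domain_pct
  }

  structure(
    list(dapi = dapi,
         markers = markers,
         background_mask = background_mask,
         truth = list(geometry = geometry,
                      epithelial_fraction_pct = params$epithelial_fraction_pct,
                      cellularity_pct = params$cellularity_pct,
                      floor_gv = floor_gv,
                      domains_pct = domains,
                      hotspot_center = hot_center),
         shape = list(center = center, semi_axes = semi_axes, coefs = coefs,
                      nuc_field = nuc_field, marker_fields = marker_fields),
         seed = seed,
         params = params),
    class = "synthetic_sample"
  )
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %s: %d x %d px, %d markers, seed %d\n",
              x$params$sample_id, x$params$height, x$params$width,
              length(x$markers), x$seed))
  invisible(x)
}

#' Generate a serial stack of synthetic sections
#'
#' All sections share one parent shape and drift away from it along a fixed
#' random direction with linearly accumulating magnitude, the way structures
#' enter and leave a slightly wedge-shaped paraffin block as it is cut:
#' section k deviates from the reference by `(k - 1) * jitter` units of
#' centre shift, axis scaling, boundary deformation and speckle-field
#' turnover. Because the deviation magnitude grows deterministically while
#' rendering is deterministic given the fields, DAPI-profile compatibility
#' decays monotonically down the stack; `jitter = 0` gives bit-identical
#' sections. At `jitter = 1` the drift is calibrated so a 30-section stack
#' keeps DAPI-profile R^2 near 0.98, the compatibility regime reported for
#' real gingiva stacks.
#'
#' @param n_sections number of sections (>= 1).
#' @param jitter per-section drift magnitude (>= 0; 1 is realistic slow
#'   drift).
#' @param params a [section_params()] list shared by all sections.
#' @param seed integer RNG seed.
#' @return list of `synthetic_sample` objects with increasing
#'   `section_index`.
#' @export
generate_serial_stack <- function(n_sections, jitter = 1,
                                  params = section_params(), seed = 1L) {
  if (n_sections < 1L) stop("n_sections must be >= 1", call. = FALSE)
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    h <- params$height; w <- params$width
    base <- list(center = c(h, w) / 2,
                 semi_axes = c(0.40 * h, 0.38 * w),
                 coefs = draw_boundary_coefs(),
                 nuc_field = gaussian_blur(matrix(stats::rnorm(h * w), h, w),
                                           1.5),
                 marker_fields = NULL)
    base$marker_fields <- lapply(params$markers, function(cfg)
      smooth_field(h, w, 40))
    names(base$marker_fields) <- vapply(params$markers, `[[`, "", "name")
    # per-unit drift direction, drawn once per stack
    delta <- list(center = stats::rnorm(2, 0, 0.12),
                  axes = stats::rnorm(2, 0, 5e-4),
                  coefs = draw_boundary_coefs(sd0 = 8e-4),
                  nuc = gaussian_blur(matrix(stats::rnorm(h * w), h, w), 1.5),
                  markers = lapply(base$marker_fields, function(f)
                    smooth_field(h, w, 40)),
                  field_eps = 0.006)
    out <- vector("list", n_sections)
    for (k in seq_len(n_sections)) {
      p <- params
      p$sample_id <- sprintf("%s-s%02d", params$sample_id, k)
      if (k > 1L && jitter == 0) {
        # zero drift: sections are bit-identical by contract
        out[[k]] <- out[[1L]]
        out[[k]]$params$sample_id <- p$sample_id
      } else {
        t_shape <- (k - 1) * jitter
        t_field <- (k - 1) * jitter * delta$field_eps
        st <- list(
          center = base$center + t_shape * delta$center,
          semi_axes = base$semi_axes * (1 + t_shape * delta$axes),
          coefs = base$coefs + t_shape * delta$coefs,
          # anchored mixing keeps unit variance: corr = 1/sqrt(1 + t^2)
          nuc_field = (base$nuc_field + t_field * delta$nuc) /
            sqrt(1 + t_field^2),
          marker_fields = Map(function(f, d) (f + t_field * d) /
                                sqrt(1 + t_field^2),
                              base$marker_fields, delta$markers)
        )
        out[[k]] <- generate_section_impl(p, seed, state = st)
      }
      out[[k]]$dapi$section_index <- k - 1L
      for (m in names(out[[k]]$markers)) {
        out[[k]]$markers[[m]]$section_index <- k - 1L
      }
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
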
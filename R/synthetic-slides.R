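#' @title Synthetic pyramidal slides
#' @description Seeded generators emulating three data regimes of a
#'   two-class slide cohort: familiar class-A/class-B texture slides, an
#'   "external-centre" colour/stain shift, and an unfamiliar
#'   (out-of-distribution) texture family. No claim of histological realism
#'   is made: the textures are tunable stand-ins whose only job is to give
#'   the pipeline two visually similar but separable classes whose
#'   discriminative pattern covers the whole tissue region.
#' @name synthetic-slides
NULL

# Rendering constants (full scale = 1.0).
.BACKGROUND_BASE <- 0.965    # near-white background, always >= 0.92
.TISSUE_RGB <- c(0.87, 0.69, 0.79) # eosin-like tissue base colour
.BLOB_RGB <- c(0.45, 0.32, 0.55)   # haematoxylin-like blob colour
.BLOB_ALPHA <- 0.55          # base blend strength of a blob
.RING_INNER_FRAC <- 0.72     # ring starts at 72% of the blob radius
.RING_GAIN <- 0.6            # ring darkening per unit ring_contrast
# centre lightening chosen so the disk-average blend strength is
# independent of ring_contrast (area-weighted balance of centre vs ring)
.CENTRE_GAIN <- .RING_GAIN * (1 - .RING_INNER_FRAC^2) / .RING_INNER_FRAC^2

#' Texture specification for one synthetic slide
#'
#' Both classes render fields of irregular dark blobs (follicle analogs)
#' with the same expected coverage; a blob either carries a darker
#' peripheral ring with a lightened centre (mantle-zone analog) or is
#' filled uniformly. The discriminative quantity is `ring_fraction`, the
#' per-slide probability that a blob is ringed: class A (the
#' lymphoma-analog, monotonous follicles) has a low fraction, class B
#' (the hyperplasia analog) a high one. The ring profile is area-balanced
#' so ringed and plain blobs share the same mean darkness: the two
#' classes share global colour statistics and differ only in blob
#' morphology. `ring_contrast` scales the ring itself (0 erases all
#' evidence); `ring_fraction` values near 0.5 give genuinely ambiguous
#' slides with conflicting evidence. `class_label = "OOD"` selects a
#' disjoint laminar band texture (no blobs).
#'
#' @param slide_id slide identifier.
#' @param class_label `"A"`, `"B"` or `"OOD"`.
#' @param centre `"internal"` or `"external"` (provenance tag only; the
#'   stain shift itself is applied by [apply_stain_shift()]).
#' @param base_size integer `(height, width)` of the level-0 image in
#'   pixels; must admit at least one 299x299 patch.
#' @param blob_density expected blob count per 10,000 px^2 of tissue.
#'   Defaults: 5.7 (class A), 4.36 (class B), chosen so both classes have
#'   equal expected blob area coverage (~0.35 of the tissue).
#' @param blob_radius_mean,blob_radius_sd blob radius distribution in
#'   pixels (defaults: A 14/3, B 16/4).
#' @param ring_fraction probability in `[0, 1]` that a blob is ringed;
#'   defaults 0.1 (class A) and 0.9 (class B).
#' @param ring_contrast fraction in `[0, 1]`; 0 makes rings invisible
#'   (classes nearly indistinguishable), larger values darken the ring and
#'   lighten the centre while preserving the disk mean.
#' @param seed integer; together with the other fields it fully determines
#'   the rendered image.
#' @return a `slide_spec` object.
#' @export
slide_spec <- function(slide_id, class_label = c("A", "B", "OOD"),
                       centre = c("internal", "external"),
                       base_size = c(4096L, 4096L),
                       blob_density = NULL, blob_radius_mean = NULL,
                       blob_radius_sd = NULL, ring_fraction = NULL,
                       ring_contrast = 0.6,
                       seed = 1L) {
  class_label <- match.arg(class_label)
  centre <- match.arg(centre)
  base_size <- as.integer(base_size)
  stopifnot(length(base_size) == 2)
  defaults <- switch(class_label,
    A = list(density = 5.7, rmean = 14, rsd = 3, rf = 0.1),
    B = list(density = 4.36, rmean = 16, rsd = 4, rf = 0.9),
    OOD = list(density = 0, rmean = 0, rsd = 0, rf = 0))
  if (is.null(blob_density)) blob_density <- defaults$density
  if (is.null(blob_radius_mean)) blob_radius_mean <- defaults$rmean
  if (is.null(blob_radius_sd)) blob_radius_sd <- defaults$rsd
  if (is.null(ring_fraction)) ring_fraction <- defaults$rf
  if (ring_contrast < 0 || ring_contrast > 1)
    stop("ring_contrast must be in [0, 1]")
  if (ring_fraction < 0 || ring_fraction > 1)
    stop("ring_fraction must be in [0, 1]")
  structure(list(slide_id = slide_id, class_label = class_label,
                 centre = centre, base_size = base_size,
                 blob_density = blob_density,
                 blob_radius_mean = blob_radius_mean,
                 blob_radius_sd = blob_radius_sd,
                 ring_fraction = ring_fraction,
                 ring_contrast = ring_contrast, seed = as.integer(seed)),
            class = "slide_spec")
}

# Smooth low-frequency field in [-1, 1], bilinear upsample of a coarse
# seeded grid; adds gentle intra-tissue colour variation.
low_freq_field <- function(H, W, cells = 8L) {
  g <- matrix(runif((cells + 1)^2, -1, 1), cells + 1, cells + 1)
  ry <- seq(0, cells, length.out = H)
  rx <- seq(0, cells, length.out = W)
  iy <- pmin(floor(ry), cells - 1); fy <- ry - iy
  ix <- pmin(floor(rx), cells - 1); fx <- rx - ix
  # bilinear: f(y, x) = (1-fy)(1-fx) g[iy,ix] + ...
  a <- g[iy + 1, ix + 1, drop = FALSE]
  b <- g[iy + 1, ix + 2, drop = FALSE]
  cc <- g[iy + 2, ix + 1, drop = FALSE]
  d <- g[iy + 2, ix + 2, drop = FALSE]
  wy <- matrix(fy, H, W)
  wx <- matrix(fx, H, W, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * cc + wx * d)
}

# Wavy-ellipse tissue region covering ~72% of the slide.
tissue_region <- function(H, W) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ay <- 0.47 * H; ax <- 0.47 * W
  phi <- runif(2, 0, 2 * pi)
  u <- matrix((seq_len(H) - cy) / ay, H, W)
  v <- matrix((seq_len(W) - cx) / ax, H, W, byrow = TRUE)
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(u, v)
  rho <= 1 + 0.05 * sin(3 * theta + phi[1]) + 0.03 * sin(5 * theta + phi[2])
}


render_slide <- function(spec) {
  H <- spec$base_size[1]; W <- spec$base_size[2]
  # background with faint pixel noise, clamped to stay >= 0.92
  bgnoise <- matrix(runif(H * W, -0.012, 0.012), H, W)
  img <- lapply(1:3, function(c) pmin(pmax(.BACKGROUND_BASE + bgnoise, 0.93), 0.995))
  tissue <- tissue_region(H, W)
  field <- low_freq_field(H, W)
  for (c in 1:3) {
    tis <- .TISSUE_RGB[c] + 0.02 * field
    img[[c]][tissue] <- tis[tissue]
  }

  if (spec$class_label == "OOD") {
    img <- render_stripes(img, tissue, H, W)
  } else if (spec$blob_density > 0) {
    img <- render_blobs(img, tissue, spec, H, W)
  }
  out <- array(0, c(H, W, 3))
  for (c in 1:3) out[, , c] <- pmin(pmax(img[[c]], 0), 1)
  out
}

render_blobs <- function(img, tissue, spec, H, W) {
  tissue_area <- sum(tissue)
  n_blobs <- round(spec$blob_density * tissue_area / 1e4)
  if (n_blobs == 0) return(img)
  # seeded rejection sampling of blob centres inside the tissue region
  centres <- matrix(0, 0, 2)
  tries <- 0L
  while (nrow(centres) < n_blobs && tries < 40L) {
    m <- 2L * (n_blobs - nrow(centres))
    cy <- ceiling(runif(m) * H); cx <- ceiling(runif(m) * W)
    ok <- tissue[cbind(cy, cx)]
    centres <- rbind(centres, cbind(cy[ok], cx[ok]))
    tries <- tries + 1L
  }
  centres <- centres[seq_len(min(nrow(centres), n_blobs)), , drop = FALSE]
  radii <- pmax(rnorm(nrow(centres), spec$blob_radius_mean, spec$blob_radius_sd), 3)
  ringed <- runif(nrow(centres)) < spec$ring_fraction
  ctr <- spec$ring_contrast
  # channels as plain local matrices so window sub-assignment is in place
  r1 <- img[[1]]; r2 <- img[[2]]; r3 <- img[[3]]
  for (i in seq_len(nrow(centres))) {
    r <- radii[i]
    y0 <- max(1, floor(centres[i, 1] - r - 1)); y1 <- min(H, ceiling(centres[i, 1] + r + 1))
    x0 <- max(1, floor(centres[i, 2] - r - 1)); x1 <- min(W, ceiling(centres[i, 2] + r + 1))
    rows <- y0:y1; cols <- x0:x1
    dy <- (rows - centres[i, 1]) / r
    dx <- (cols - centres[i, 2]) / r
    d <- sqrt(outer(dy^2, dx^2, `+`))
    edge <- pmin(pmax((1 - d) / 0.08, 0), 1) # soft anti-aliased rim
    w <- if (ringed[i]) {
      ifelse(d < .RING_INNER_FRAC, 1 - ctr * .CENTRE_GAIN, 1 + ctr * .RING_GAIN)
    } else 1
    alpha <- .BLOB_ALPHA * w * edge
    alpha[!tissue[rows, cols]] <- 0 # blobs never spill onto background
    keep <- 1 - alpha
    r1[rows, cols] <- r1[rows, cols] * keep + .BLOB_RGB[1] * alpha
    r2[rows, cols] <- r2[rows, cols] * keep + .BLOB_RGB[2] * alpha
    r3[rows, cols] <- r3[rows, cols] * keep + .BLOB_RGB[3] * alpha
  }
  list(r1, r2, r3)
}

# Disjoint texture family for OOD slides: laminar dark bands (no blobs),
# rendered from the same "material" as the blob classes. Alternating bands
# carry the darker-edge / lightened-core transverse profile of a ringed
# blob or the uniform fill of a plain blob, so an unfamiliar architecture
# is built from locally familiar evidence (the analog of a different
# lesion under the same stain).
render_stripes <- function(img, tissue, H, W) {
  theta <- runif(1, 0, pi)
  lambda <- runif(1, 55, 80) # band period ~ 2 blob diameters
  phase <- runif(1, 0, 2 * pi)
  ctr <- 0.6
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  u <- 2 * pi * (y * cos(theta) + x * sin(theta)) / lambda + phase
  s <- sin(u)                      # > 0 inside a band
  band <- floor(u / (2 * pi))      # band index; parity picks the profile
  inside <- s > 0
  edge_zone <- inside & s < 0.45   # transverse border of the band
  w <- matrix(1, H, W)
  ringed_band <- band %% 2 == 0
  w[inside & ringed_band & edge_zone] <- 1 + ctr * .RING_GAIN
  w[inside & ringed_band & !edge_zone] <- 1 - ctr * .CENTRE_GAIN
  alpha <- ifelse(inside, .BLOB_ALPHA * w, 0)
  alpha[!tissue] <- 0
  for (c in 1:3) {
    img[[c]] <- img[[c]] * (1 - alpha) + .BLOB_RGB[c] * alpha
  }
  img
}

#' Generate one synthetic pyramidal slide
#'
#' Renders the base image described by a [slide_spec()] (tissue region
#' covering >= 60% of the slide, class-characteristic texture across the
#' whole tissue region) and builds its resolution pyramid. The output is a
#' pure function of the spec: the same spec yields bit-identical pixels.
#'
#' @param spec a `slide_spec`.
#' @param n_levels number of pyramid levels (default 3).
#' @param base_resolution declared level-0 resolution (default 0.49
#'   micrometres/pixel, so the usual level arithmetic applies unchanged).
#' @return a `slide_pyramid`.
#' @export
generate_slide <- function(spec, n_levels = 3L, base_resolution = 0.49) {
  stopifnot(inherits(spec, "slide_spec"))
  if (any(spec$base_size < 299L))
    stop("base_size ", paste(spec$base_size, collapse = "x"),
         " is too small for one 299x299 patch at level 0")
  base <- local_seed(mix_seed(spec$seed, "render", spec$slide_id,
                              spec$class_label),
                     render_slide(spec))
  build_pyramid(base, n_levels, base_resolution, slide_id = spec$slide_id)
}

#' Generate an out-of-distribution slide
#'
#' Convenience wrapper: a slide whose texture is drawn from a family
#' disjoint from classes A and B (laminar stripes, no blobs).
#'
#' @inheritParams generate_slide
#' @param slide_id slide identifier.
#' @param seed integer seed.
#' @param base_size integer `(height, width)` in pixels.
#' @return a `slide_pyramid`.
#' @export
generate_ood_slide <- function(slide_id, seed, base_size = c(4096L, 4096L),
                               n_levels = 3L, base_resolution = 0.49) {
  spec <- slide_spec(slide_id, "OOD", base_size = base_size, seed = seed)
  generate_slide(spec, n_levels = n_levels, base_resolution = base_resolution)
}

#' Stain shift parameters
#'
#' A simple "external centre" re-processing model: per-channel linear gain
#' and offset followed by an optional isotropic Gaussian blur. The identity
#' shift (`gain = 1`, `offset = 0`, `blur_sigma = 0`) leaves images
#' bit-identical. The default is a noticeable eosin-heavy, colour-only
#' shift (staining protocols change colour balance; no optical blur) used
#' for the synthetic external-centre regime.
#'
#' @param channel_gain positive length-3 multiplicative gains (R, G, B).
#' @param channel_offset length-3 additive offsets in `[-0.2, 0.2]`.
#' @param blur_sigma Gaussian blur standard deviation in pixels (>= 0).
#' @return a `stain_shift` object.
#' @export
stain_shift <- function(channel_gain = c(1.08, 0.92, 1.02),
                        channel_offset = c(0.02, -0.03, 0.01),
                        blur_sigma = 0) {
  if (any(channel_gain <= 0)) stop("channel_gain must be positive")
  stopifnot(length(channel_gain) == 3, length(channel_offset) == 3,
            all(abs(channel_offset) <= 0.2), blur_sigma >= 0)
  structure(list(channel_gain = channel_gain,
                 channel_offset = channel_offset,
                 blur_sigma = blur_sigma),
            class = "stain_shift")
}

identity_shift <- function() stain_shift(c(1, 1, 1), c(0, 0, 0), 0)

# Separable Gaussian blur with edge renormalisation (kernel mass outside
# the image is dropped and the remaining weights rescaled).
gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  blur_1d <- function(mat, kern) {
    n <- nrow(mat)
    acc <- matrix(0, n, ncol(mat))
    wsum <- numeric(n)
    for (o in seq_along(kern)) {
      off <- o - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      acc[ok, ] <- acc[ok, ] + kern[o] * mat[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + kern[o]
    }
    acc / wsum
  }
  t(blur_1d(t(blur_1d(m, k)), k))
}

#' Apply a stain shift to a pyramid
#'
#' Each level is transformed pixelwise by `gain * x + offset` per channel,
#' blurred (if `blur_sigma > 0`), and clipped to `[0, 1]`. Dimensions are
#' unchanged; an identity shift returns the input bit-identically.
#'
#' @param pyramid a `slide_pyramid`.
#' @param shift a [stain_shift()].
#' @return the transformed `slide_pyramid`.
#' @export
apply_stain_shift <- function(pyramid, shift) {
  stopifnot(inherits(pyramid, "slide_pyramid"), inherits(shift, "stain_shift"))
  if (all(shift$channel_gain == 1) && all(shift$channel_offset == 0) &&
      shift$blur_sigma == 0) {
    return(pyramid)
  }
  pyramid$levels <- lapply(pyramid$levels, function(img) {
    if (is.null(img)) return(NULL)
    out <- img
    for (c in 1:3) {
      ch <- img[, , c] * shift$channel_gain[c] + shift$channel_offset[c]
      ch <- gaussian_blur_matrix(ch, shift$blur_sigma)
      out[, , c] <- pmin(pmax(ch, 0), 1)
    }
    out
  })
  pyramid
}
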
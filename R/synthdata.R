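#' Specification for a synthetic multi-stain patch dataset
#'
#' Describes K latent tissue classes rendered consistently across
#' `n_stains` pseudo-stain RGB triplets.  Every class owns a texture field
#' (oriented stripe/blob pattern with class-specific frequency and
#' orientation) and per-stain colour offsets; the same texture geometry is
#' shared by all stains of a patch, emulating co-registered sections of one
#' tissue that merely take up stain differently.
#'
#' `separation` scales every class-specific effect: at `separation = 0` all
#' classes are statistically indistinguishable, and class distinguishability
#' grows monotonically with it.  `noise_sd` is the standard deviation of
#' additive Gaussian pixel noise (intensity units, image range is `[0, 1]`).
#'
#' @param n_classes number of latent classes `K` (>= 1).
#' @param n_patches number of patches to generate (>= 0).
#' @param patch_size patch side length in pixels (>= 8).
#' @param n_stains number of pseudo-stains (default 5, mirroring the
#'   HE / MT / CD31 / CK19 / Ki67 panel).
#' @param separation non-negative class-separation scale (default 1,
#'   a strongly separated regime).
#' @param noise_sd non-negative pixel noise scale (default 0.05).
#' @param seed integer RNG seed; identical specs give bit-identical data.
#'
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_classes, n_patches, patch_size = 64L, n_stains = 5L,
                       separation = 1, noise_sd = 0.05, seed = 1L) {
  if (n_classes < 1) abort("`n_classes` must be >= 1")
  if (n_patches < 0) abort("`n_patches` must be >= 0")
  if (patch_size < 8) abort("`patch_size` must be >= 8")
  if (n_stains < 1) abort("`n_stains` must be >= 1")
  if (separation < 0 || noise_sd < 0)
    abort("`separation` and `noise_sd` must be non-negative")
  structure(list(n_classes = as.integer(n_classes),
                 n_patches = as.integer(n_patches),
                 patch_size = as.integer(patch_size),
                 n_stains = as.integer(n_stains),
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Base colours of the five-stain panel (RGB in [0,1]); extra stains get
# evenly spaced hues.
stain_base_colors <- function(n_stains) {
  panel <- rbind(
    he   = c(0.80, 0.62, 0.74),
    mt   = c(0.55, 0.57, 0.78),
    cd31 = c(0.72, 0.60, 0.52),
    ck19 = c(0.66, 0.52, 0.44),
    ki67 = c(0.78, 0.70, 0.62)
  )
  if (n_stains <= 5L) return(panel[seq_len(n_stains), , drop = FALSE])
  extra <- t(grDevices::col2rgb(
    grDevices::hsv(seq(0, 1 - 1 / (n_stains - 5L), length.out = n_stains - 5L),
                   0.25, 0.7)) / 255)
  rbind(panel, extra)
}

# Deterministic class appearance parameters for a spec: per-class per-channel
# colour offsets (mu), texture contrasts (beta), and texture geometry.
synth_class_params <- function(spec) {
  K <- spec$n_classes
  C <- 3L * spec$n_stains
  with_seed(spec$seed, {
    list(
      bg    = as.vector(t(stain_base_colors(spec$n_stains))),
      mu    = matrix(runif(K * C, -0.3, 0.3), K, C),
      beta  = matrix(runif(K * C, -0.4, 0.4), K, C),
      freq  = 3 + spec$separation * runif(K, -1.5, 1.5),
      # orientations fan out with separation and coincide at separation 0
      theta = seq(0, pi, length.out = K + 1L)[seq_len(K)] *
        min(spec$separation, 1)
    )
  })
}

# Render patches for a vector of 0-based labels under the RNG stream `seed`.
render_synth_patches <- function(labels, spec, seed) {
  S <- spec$patch_size
  C <- 3L * spec$n_stains
  n <- length(labels)
  pars <- synth_class_params(spec)
  data <- array(0, dim = c(S, S, C, n))
  if (n == 0L) return(data)
  xs <- matrix(rep(seq(0, 1, length.out = S), each = S), S, S)   # column coord
  ys <- matrix(rep(seq(0, 1, length.out = S), times = S), S, S)  # row coord
  proj <- lapply(seq_len(spec$n_classes), function(k)
    xs * cos(pars$theta[k]) + ys * sin(pars$theta[k]))
  with_seed(seed, {
    for (i in seq_len(n)) {
      k <- labels[i] + 1L
      phase <- runif(1, 0, 2 * pi)
      blob_phase <- runif(2, 0, 2 * pi)
      tex <- 0.5 + 0.35 * sin(2 * pi * pars$freq[k] * proj[[k]] + phase) +
        0.15 * sin(2 * pi * (xs + ys) + blob_phase[1]) *
        sin(2 * pi * (xs - ys) + blob_phase[2])
      tc <- as.vector(tex) - 0.5
      m <- outer(tc, spec$separation * pars$beta[k, ])
      m <- sweep(m, 2, pars$bg + spec$separation * pars$mu[k, ], "+")
      if (spec$noise_sd > 0)
        m <- m + rnorm(length(m), 0, spec$noise_sd)
      data[, , , i] <- array(pmin(pmax(m, 0), 1), dim = c(S, S, C))
    }
  })
  data
}

#' Generate a synthetic multi-stain patch dataset
#'
#' Draws near-uniform class labels (round-robin, then shuffled) and renders
#' each patch as `n_stains` co-registered RGB renditions of one underlying
#' texture field.  Identical specs (including seed) give bit-identical output.
#'
#' @param spec a [synth_spec()].
#' @return A [new_patchset()] with `labels` set to the true 0-based classes.
#' @export
generate_patch_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_patches
  labels <- integer(0)
  if (n > 0L) {
    labels <- rep_len(seq_len(spec$n_classes) - 1L, n)
    labels <- with_seed(spec$seed %% 1000000000L + 1L, sample(labels))
  }
  data <- render_synth_patches(labels, spec, spec$seed %% 1000000000L + 2L)
  new_patchset(data, labels = labels, n_stains = spec$n_stains,
               source_id = "synthetic")
}

#' Specification for a synthetic tiled whole-slide image
#'
#' @param height_px,width_px image dimensions in pixels.
#' @param tile_size tile side length; must fit inside the image at least once.
#' @param class_map optional integer matrix (`floor(height/tile)` x
#'   `floor(width/tile)`) of 0-based class ids, row-major tile layout.
#'   If `NULL`, a random map over `n_classes` is drawn at generation time.
#' @return A `synth_wsi_spec` list.
#' @export
synth_wsi_spec <- function(height_px, width_px, tile_size, class_map = NULL) {
  if (tile_size > min(height_px, width_px))
    abort("`tile_size` exceeds the image extent")
  nr <- height_px %/% tile_size
  nc <- width_px %/% tile_size
  if (!is.null(class_map)) {
    class_map <- as.matrix(class_map)
    if (!all(dim(class_map) == c(nr, nc)))
      abort(sprintf("`class_map` must be %d x %d for these dimensions", nr, nc))
    storage.mode(class_map) <- "integer"
  }
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 tile_size = as.integer(tile_size),
                 n_rows = nr, n_cols = nc, class_map = class_map),
            class = "synth_wsi_spec")
}

#' Generate a synthetic whole-slide stain stack with a known class map
#'
#' Each non-overlapping tile of the output image is one patch rendered from
#' its `class_map` entry, so sequentially re-cutting the image recovers the
#' generated tiles exactly.  Remainder strips beyond the tiled region are
#' filled with the stain base colours.
#'
#' @param wsi_spec a [synth_wsi_spec()].
#' @param spec a [synth_spec()] describing class appearance (its
#'   `patch_size` is ignored; tiles use `wsi_spec$tile_size`).
#' @return A list with class `synthetic_wsi`: `image` (H x W x C array),
#'   `class_map` (matrix of 0-based ids) and `tile_size`.
#' @export
generate_synthetic_wsi <- function(wsi_spec, spec) {
  stopifnot(inherits(wsi_spec, "synth_wsi_spec"), inherits(spec, "synth_spec"))
  nr <- wsi_spec$n_rows; nc <- wsi_spec$n_cols
  ts <- wsi_spec$tile_size
  cmap <- wsi_spec$class_map
  if (is.null(cmap)) {
    cmap <- with_seed(spec$seed %% 1000000000L + 3L,
                      matrix(sample.int(spec$n_classes, nr * nc, replace = TRUE) - 1L,
                             nr, nc))
  }
  tile_spec <- spec
  tile_spec$patch_size <- ts
  labels <- as.integer(t(cmap))  # row-major tile order
  tiles <- render_synth_patches(labels, tile_spec, spec$seed %% 1000000000L + 4L)
  C <- 3L * spec$n_stains
  img <- array(rep(rep(synth_class_params(spec)$bg, each = wsi_spec$height_px *
                         wsi_spec$width_px), 1),
               dim = c(wsi_spec$height_px, wsi_spec$width_px, C))
  i <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    i <- i + 1L
    img[(r - 1L) * ts + seq_len(ts), (cc - 1L) * ts + seq_len(ts), ] <-
      tiles[, , , i]
  }
  structure(list(image = img, class_map = cmap, tile_size = ts,
                 n_stains = spec$n_stains),
            class = "synthetic_wsi")
}

#' @export
print.synthetic_wsi <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<synthetic_wsi> %dx%d px, %d channels, %dx%d tiles of %d px\n",
              d[1], d[2], d[3], nrow(x$class_map), ncol(x$class_map),
              x$tile_size))
  invisible(x)
}
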
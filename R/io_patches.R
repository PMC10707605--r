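#' Non-overlapping tile grid over a whole-slide image
#'
#' Tiles are square, disjoint, row-major ordered, with 0-based anchors at
#' `(r * tile_size, c * tile_size)`; remainder strips that cannot hold a full
#' tile are discarded.  A 15000 x 20000 px slide at tile size 128 yields
#' `117 * 156 = 18252` tiles.
#'
#' @param height_px,width_px image dimensions in pixels (positive).
#' @param tile_size tile side length in pixels (positive).
#' @return A `tile_grid` list with `n_rows`, `n_cols`, `count`, and an
#'   `anchors` tibble (`tile`, `row`, `col` — 0-based pixel anchors,
#'   row-major order).
#' @export
tile_grid <- function(height_px, width_px, tile_size) {
  if (tile_size <= 0) abort("`tile_size` must be positive")
  if (height_px <= 0 || width_px <= 0) abort("image dimensions must be positive")
  nr <- as.integer(height_px %/% tile_size)
  nc <- as.integer(width_px %/% tile_size)
  count <- nr * nc
  anchors <- if (count > 0) {
    tibble(
      tile = seq_len(count),
      row = rep(seq_len(nr) - 1L, each = nc) * as.integer(tile_size),
      col = rep(seq_len(nc) - 1L, times = nr) * as.integer(tile_size)
    )
  } else tibble(tile = integer(), row = integer(), col = integer())
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 tile_size = as.integer(tile_size),
                 n_rows = nr, n_cols = nc, count = count, anchors = anchors),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %dx%d px at tile %d: %d x %d = %d tiles\n",
              x$height_px, x$width_px, x$tile_size, x$n_rows, x$n_cols,
              x$count))
  invisible(x)
}

#' Cut sequential non-overlapping tiles from a stain-stack image
#'
#' @param image `H x W x C` array in `[0, 1]` (C = 3 * n_stains).
#' @param tile_size tile side length.
#' @return A [new_patchset()] of `tile_grid(H, W, tile_size)$count` patches in
#'   row-major tile order, with `positions` recording the 0-based anchors.
#' @export
cut_tiles <- function(image, tile_size) {
  d <- dim(image)
  g <- tile_grid(d[1], d[2], tile_size)
  data <- array(0, dim = c(tile_size, tile_size, d[3], g$count))
  for (i in seq_len(g$count)) {
    r0 <- g$anchors$row[i]; c0 <- g$anchors$col[i]
    data[, , , i] <- image[r0 + seq_len(tile_size), c0 + seq_len(tile_size), ]
  }
  new_patchset(data, positions = cbind(g$anchors$row, g$anchors$col),
               n_stains = d[3] / 3L)
}

#' Sample random patches from a stain-stack image
#'
#' Anchors are sampled uniformly with replacement over all valid positions;
#' the same anchor is applied to every stain channel, preserving
#' co-registration.
#'
#' @param image `H x W x C` array in `[0, 1]`.
#' @param n number of patches.
#' @param size patch side length; must not exceed either image dimension.
#' @param seed integer RNG seed (reproducible anchors).
#' @return A [new_patchset()] with `positions` holding 0-based anchors.
#' @export
sample_random_patches <- function(image, n, size, seed = 1L) {
  d <- dim(image)
  if (size > min(d[1], d[2])) abort("`size` exceeds the image extent")
  if (n == 0L) {
    return(new_patchset(array(0, dim = c(size, size, d[3], 0L)),
                        positions = matrix(integer(), 0, 2),
                        n_stains = d[3] / 3L))
  }
  anchors <- with_seed(seed, cbind(
    sample.int(d[1] - size + 1L, n, replace = TRUE) - 1L,
    sample.int(d[2] - size + 1L, n, replace = TRUE) - 1L
  ))
  data <- array(0, dim = c(size, size, d[3], n))
  for (i in seq_len(n)) {
    data[, , , i] <- image[anchors[i, 1] + seq_len(size),
                           anchors[i, 2] + seq_len(size), ]
  }
  new_patchset(data, positions = anchors, n_stains = d[3] / 3L)
}

#' Effective pixel resolution after linear rescaling
#'
#' Scanning at `base_um_per_px` and shrinking the image to a linear fraction
#' `linear_scale` of its original side coarsens the sampling: the effective
#' resolution is `base_um_per_px / linear_scale`.  For a 20x scan at
#' 0.22 um/px reduced by 30% (scale 0.70) this gives 0.31 um/px (2 dp).
#'
#' @param base_um_per_px native scan resolution in micrometres per pixel.
#' @param linear_scale linear size fraction retained, in `(0, 1]`.
#' @return Effective resolution in micrometres per pixel.
#' @export
effective_resolution <- function(base_um_per_px, linear_scale) {
  if (base_um_per_px <= 0 || linear_scale <= 0)
    abort("inputs must be positive")
  if (linear_scale > 1) abort("`linear_scale` must be in (0, 1]")
  base_um_per_px / linear_scale
}

#' Normalize an integer image array to [0, 1]
#'
#' Integer images are divided by the maximum of their storage type
#' (255 for 8-bit, 65535 for 16-bit); floating-point input is returned
#' unchanged after a range check.
#'
#' @param image numeric or integer array.
#' @param bit_depth bits per sample for integer input (8 or 16).
#' @return Numeric array with values in `[0, 1]`.
#' @export
normalize_pixels <- function(image, bit_depth = 8L) {
  if (is.integer(image) || max(image, na.rm = TRUE) > 1 + 1e-8) {
    denom <- 2^bit_depth - 1
    image <- image / denom
  }
  if (min(image) < -1e-8 || max(image) > 1 + 1e-8)
    abort("normalized values fall outside [0, 1]; check `bit_depth`")
  array(as.numeric(image), dim = dim(image))
}

#' Default stain stacking order
#'
#' Channel triplets are stacked in the fixed order HE, MT, CD31, CK19, Ki67
#' unless overridden, giving deterministic channel semantics.
#'
#' @return Character vector of stain names.
#' @export
stain_order <- function() c("HE", "MT", "CD31", "CK19", "Ki67")

#' Read a co-registered multi-stain stack from per-stain image files
#'
#' @param paths character vector of TIFF or PNG files, one RGB image per
#'   stain, in the desired stacking order (see [stain_order()]).
#' @return `H x W x (3 * length(paths))` array in `[0, 1]`.
#' @export
read_stain_stack <- function(paths) {
  imgs <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    img <- switch(ext,
      "png" = png::readPNG(p),
      "tif" = ,
      "tiff" = tiff::readTIFF(p),
      abort(sprintf("unsupported image format: %s", ext)))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
  d <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) all(dim(i)[1:2] == d[1:2]), logical(1))))
    abort("stain images are not co-registered (dimensions differ)")
  array(unlist(imgs), dim = c(d[1], d[2], 3L * length(imgs)))
}

#' Write a patch set to disk
#'
#' Pixel data go to one multi-page TIFF (one 3-channel page per stain per
#' patch, patch-major) and labels/anchors to a CSV sidecar.
#'
#' @param ps a `stain_patchset`.
#' @param path output TIFF path; the sidecar is `<path>.csv`.
#' @return `path`, invisibly.
#' @export
write_patchset <- function(ps, path) {
  d <- dim(ps$data)
  pages <- list()
  for (i in seq_len(d[4]))
    for (s in seq_len(ps$n_stains))
      pages[[length(pages) + 1L]] <-
        ps$data[, , (s - 1L) * 3L + 1:3, i, drop = TRUE]
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- as_tibble(ps)[, c("patch", "label", "row", "col")]
  utils::write.csv(meta, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Read a patch set written by [write_patchset()]
#'
#' @param path TIFF path previously given to [write_patchset()].
#' @param n_stains number of stains per patch.
#' @return A `stain_patchset`.
#' @export
read_patchset <- function(path, n_stains = 5L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- length(pages) %/% n_stains
  d <- dim(pages[[1]])
  data <- array(0, dim = c(d[1], d[2], 3L * n_stains, n))
  for (i in seq_len(n))
    for (s in seq_len(n_stains))
      data[, , (s - 1L) * 3L + 1:3, i] <- pages[[(i - 1L) * n_stains + s]]
  meta_path <- paste0(path, ".csv")
  labels <- positions <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path)
    if (!all(is.na(meta$label))) labels <- meta$label
    if (!all(is.na(meta$row))) positions <- cbind(meta$row, meta$col)
  }
  new_patchset(data, labels = labels, positions = positions,
               n_stains = n_stains)
}
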
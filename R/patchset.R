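#' Multi-stain patch set
#'
#' A `stain_patchset` bundles a batch of co-registered multi-stain image
#' patches with optional ground-truth labels and source anchors.  Pixel data
#' live in a 4-D array with dimensions `(H, W, C, N)` where `C = 3 * n_stains`
#' (each stain contributes an RGB triplet) and all values lie in `[0, 1]`.
#'
#' Cluster and class identifiers are 0-based integers throughout the package.
#'
#' @param data numeric 4-D array `(H, W, C, N)` with values in `[0, 1]`.
#' @param labels optional integer vector of length `N` (0-based class ids).
#' @param positions optional integer matrix `N x 2` of `(row, col)` 0-based
#'   anchors in the source image.
#' @param source_id optional character identifier of the source slide.
#' @param n_stains number of stains; `C` must equal `3 * n_stains`.
#'
#' @return A `stain_patchset` object.
#' @export
new_patchset <- function(data, labels = NULL, positions = NULL,
                         source_id = NULL, n_stains = dim(data)[3] / 3L) {
  if (length(dim(data)) != 4L)
    abort("`data` must be a 4-D (H, W, C, N) array.")
  if (dim(data)[3] != 3L * n_stains)
    abort(sprintf("channel count %d != 3 * n_stains (%d)",
                  dim(data)[3], 3L * n_stains))
  n <- dim(data)[4]
  if (n > 0L) {
    rng <- range(data)
    if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
      abort("patch values must lie in [0, 1]")
  }
  if (!is.null(labels)) {
    if (length(labels) != n) abort("`labels` length must equal patch count")
    labels <- as.integer(labels)
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != n || ncol(positions) != 2L)
      abort("`positions` must be an N x 2 matrix")
  }
  structure(
    list(data = data, labels = labels, positions = positions,
         source_id = source_id, n_stains = as.integer(n_stains)),
    class = "stain_patchset"
  )
}

#' @export
print.stain_patchset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<stain_patchset> %d patches, %dx%d px, %d channels (%d stains)%s\n",
    d[4], d[1], d[2], d[3], x$n_stains,
    if (!is.null(x$labels)) sprintf(", %d labelled classes",
                                    length(unique(x$labels))) else ""))
  invisible(x)
}

#' @export
length.stain_patchset <- function(x) dim(x$data)[4]

#' Subset a patch set
#'
#' @param x a `stain_patchset`.
#' @param i patch indices (1-based, as usual for R subsetting).
#' @param ... unused.
#' @return A `stain_patchset` with the selected patches.
#' @export
`[.stain_patchset` <- function(x, i, ...) {
  new_patchset(x$data[, , , i, drop = FALSE],
               labels = if (!is.null(x$labels)) x$labels[i],
               positions = if (!is.null(x$positions)) x$positions[i, , drop = FALSE],
               source_id = x$source_id, n_stains = x$n_stains)
}

#' Combine two patch sets along the patch dimension
#'
#' @param a,b `stain_patchset` objects with identical patch geometry.
#' @return A `stain_patchset` holding the patches of `a` followed by `b`.
#' @export
concat_patchsets <- function(a, b) {
  da <- dim(a$data); db <- dim(b$data)
  if (!all(da[1:3] == db[1:3])) abort("patch geometries differ")
  dat <- array(c(a$data, b$data), dim = c(da[1:3], da[4] + db[4]))
  lab <- if (!is.null(a$labels) && !is.null(b$labels)) c(a$labels, b$labels)
  new_patchset(dat, labels = lab, n_stains = a$n_stains)
}

#' Summarise a patch set as a tibble
#'
#' One row per patch: label, anchor and per-patch mean intensity.
#'
#' @param x a `stain_patchset`.
#' @param ... unused.
#' @return A tibble with columns `patch`, `label`, `row`, `col`, `mean_intensity`.
#' @export
as_tibble.stain_patchset <- function(x, ...) {
  n <- length(x)
  means <- if (n > 0) apply(x$data, 4, mean) else numeric()
  tibble(
    patch = seq_len(n),
    label = if (!is.null(x$labels)) x$labels else NA_integer_,
    row = if (!is.null(x$positions)) x$positions[, 1] else NA_integer_,
    col = if (!is.null(x$positions)) x$positions[, 2] else NA_integer_,
    mean_intensity = means
  )
}

#' Per-patch channel-mean feature matrix
#'
#' Collapses each patch to its vector of per-channel mean intensities, the
#' raw-pixel feature space used by the synthetic-data sanity checks.
#'
#' @param ps a `stain_patchset`.
#' @return An `N x C` numeric matrix.
#' @export
patch_channel_means <- function(ps) {
  d <- dim(ps$data)
  if (d[4] == 0L) return(matrix(numeric(), 0, d[3]))
  t(apply(ps$data, 4, function(a) colMeans(matrix(a, d[1] * d[2], d[3]))))
}
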
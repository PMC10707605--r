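#' Ranges for random affine augmentation
#'
#' Rotation, translation and scaling only (no shear, no colour jitter).
#' Defaults are mild enough to preserve class identity: angle within
#' +/- 30 degrees, shift within +/- 10% of the side per axis, scale in
#' `[0.9, 1.1]`.
#'
#' @param angle_deg length-2 numeric, rotation range in degrees.
#' @param shift_frac length-2 numeric, translation range as a fraction of the
#'   patch side (applied independently per axis).
#' @param scale length-2 positive numeric, isotropic scale range.
#' @return An `affine_ranges` list.
#' @export
affine_ranges <- function(angle_deg = c(-30, 30), shift_frac = c(-0.1, 0.1),
                          scale = c(0.9, 1.1)) {
  if (any(scale <= 0)) abort("`scale` range must be positive")
  structure(list(angle_deg = sort(angle_deg), shift_frac = sort(shift_frac),
                 scale = sort(scale)), class = "affine_ranges")
}

#' Apply a random affine transform to every patch
#'
#' One transform (angle, per-axis shift, isotropic scale) is sampled per
#' patch and applied identically to all of its channels, so the stain
#' renditions stay co-registered.  Interpolation is bilinear with mirror
#' padding; with identity parameters the output equals the input exactly.
#'
#' @param ps a `stain_patchset`.
#' @param ranges an [affine_ranges()].
#' @param seed integer RNG seed (reproducible transforms).
#' @return A `stain_patchset` of the same shape.
#' @export
random_affine <- function(ps, ranges = affine_ranges(), seed = 1L) {
  d <- dim(ps$data)
  n <- d[4]
  if (n == 0L) return(ps)
  params <- with_seed(seed, rbind(
    runif(n, ranges$angle_deg[1], ranges$angle_deg[2]) * pi / 180,
    runif(n, ranges$shift_frac[1], ranges$shift_frac[2]) * d[1],
    runif(n, ranges$shift_frac[1], ranges$shift_frac[2]) * d[2],
    runif(n, ranges$scale[1], ranges$scale[2])
  ))
  out <- cpp_affine_warp(ps$data, params)
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- d
  new_patchset(out, labels = ps$labels, positions = ps$positions,
               source_id = ps$source_id, n_stains = ps$n_stains)
}

#' Apply one fixed affine transform to every patch
#'
#' Deterministic counterpart of [random_affine()], useful for testing and
#' for visualizing the augmentation.
#'
#' @param ps a `stain_patchset`.
#' @param angle_deg rotation in degrees.
#' @param shift_frac length-2 shift as a fraction of the side (row, col).
#' @param scale isotropic scale factor (> 0).
#' @return A `stain_patchset` of the same shape.
#' @export
affine_transform <- function(ps, angle_deg = 0, shift_frac = c(0, 0),
                             scale = 1) {
  if (scale <= 0) abort("`scale` must be positive")
  d <- dim(ps$data)
  n <- d[4]
  if (n == 0L) return(ps)
  params <- matrix(rep(c(angle_deg * pi / 180, shift_frac[1] * d[1],
                         shift_frac[2] * d[2], scale), n), 4, n)
  out <- cpp_affine_warp(ps$data, params)
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- d
  new_patchset(out, labels = ps$labels, positions = ps$positions,
               source_id = ps$source_id, n_stains = ps$n_stains)
}
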
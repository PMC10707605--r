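#' Embed latent features in two dimensions
#'
#' Projects the upper-latent embedding matrix to 2-D with a nonlinear
#' manifold routine for visual inspection of the cluster structure.  The
#' default routine is Kruskal non-metric multidimensional scaling
#' (`MASS::isoMDS`) on Euclidean distances, initialized from classical MDS,
#' which makes the result deterministic; `method = "cmdscale"` gives the
#' plain classical (metric) solution.  Row order is preserved.
#'
#' @param features `N x D` numeric matrix, `N >= 10`.
#' @param seed integer seed (kept for interface stability; the default
#'   routine is deterministic).
#' @param method `"nmds"` (default) or `"cmdscale"`.
#' @return `N x 2` coordinate matrix.
#' @export
embed_2d <- function(features, seed = 1L, method = c("nmds", "cmdscale")) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) < 10L) abort("need at least 10 points to embed")
  d <- stats::dist(features)
  if (min(d) == 0) d <- d + 1e-9  # isoMDS rejects zero distances
  init <- stats::cmdscale(d, k = 2L)
  coords <- switch(method,
    nmds = with_seed(seed, MASS::isoMDS(d, y = init, k = 2L, trace = FALSE)$points),
    cmdscale = init)
  dimnames(coords) <- NULL
  coords
}

#' Categorical palette for cluster colours
#'
#' A fixed 20-colour categorical palette indexed by 0-based cluster id;
#' distinct ids never share a colour (ids beyond 20 recycle with darkened
#' variants).
#'
#' @param n number of colours needed.
#' @return Character vector of hex colours of length `n`.
#' @export
cluster_palette <- function(n) {
  base <- c(
    "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
    "#e377c2", "#7f7f7f", "#bcbd22", "#17becf", "#aec7e8", "#ffbb78",
    "#98df8a", "#ff9896", "#c5b0d5", "#c49c94", "#f7b6d2", "#c7c7c7",
    "#dbdb8d", "#9edae5")
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- grDevices::adjustcolor(rep(base, length.out = n - length(base)),
                                  red.f = 0.6, green.f = 0.6, blue.f = 0.6)
  c(base, extra)
}

#' Build a per-tile cluster map for a tiled whole-slide image
#'
#' Fills the tile grid row-major with the given per-tile cluster labels,
#' tallies the per-cluster histogram (counts always sum to `grid$count`),
#' and attaches a palette.
#'
#' @param grid a [tile_grid()].
#' @param labels integer vector of 0-based cluster ids, length `grid$count`,
#'   row-major tile order.
#' @param palette optional id -> colour character vector (1-indexed by
#'   `id + 1`); defaults to [cluster_palette()].
#' @return A `cluster_map`: list with `grid` (label matrix `n_rows x
#'   n_cols`), `palette`, `histogram` (tibble `cluster`, `n`) and `tile_size`.
#' @export
build_cluster_map <- function(grid, labels, palette = NULL) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(labels) != grid$count)
    abort(sprintf("need %d labels, got %d", grid$count, length(labels)))
  labels <- as.integer(labels)
  k <- max(labels) + 1L
  if (is.null(palette)) palette <- cluster_palette(k)
  if (k > length(palette)) abort("label outside palette")
  if (anyDuplicated(palette[seq_len(k)]))
    abort("palette must give distinct clusters distinct colours")
  lab_mat <- matrix(labels, grid$n_rows, grid$n_cols, byrow = TRUE)
  hist <- tibble(cluster = seq_len(k) - 1L,
                 n = tabulate(labels + 1L, nbins = k))
  structure(list(grid = lab_mat, palette = palette, histogram = hist,
                 tile_size = grid$tile_size),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d x %d tiles, %d clusters present\n",
              nrow(x$grid), ncol(x$grid), sum(x$histogram$n > 0)))
  invisible(x)
}

#' Render a cluster map as an RGB raster
#'
#' @param map a [build_cluster_map()] result.
#' @param px_per_tile pixels per tile side in the rendering (default 1;
#'   use `map$tile_size` for a full-size overlay).
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
render_cluster_map <- function(map, px_per_tile = 1L) {
  rgb_cols <- grDevices::col2rgb(map$palette) / 255
  nr <- nrow(map$grid) * px_per_tile
  nc <- ncol(map$grid) * px_per_tile
  big <- map$grid[rep(seq_len(nrow(map$grid)), each = px_per_tile),
                  rep(seq_len(ncol(map$grid)), each = px_per_tile),
                  drop = FALSE]
  out <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(rgb_cols[ch, big + 1L], nr, nc)
  out
}

#' Write a rendered cluster map to PNG
#'
#' @inheritParams render_cluster_map
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_cluster_map_png <- function(map, path, px_per_tile = 1L) {
  png::writePNG(render_cluster_map(map, px_per_tile), path)
  invisible(path)
}

#' @export
as_tibble.cluster_map <- function(x, ...) {
  tibble(
    row = rep(seq_len(nrow(x$grid)) - 1L, times = ncol(x$grid)),
    col = rep(seq_len(ncol(x$grid)) - 1L, each = nrow(x$grid)),
    cluster = as.integer(x$grid)
  )
}

#' Plot a cluster map
#'
#' @param object a `cluster_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_map <- function(object, ...) {
  df <- as_tibble(object)
  k <- length(unique(df$cluster))
  pal <- setNames(object$palette[sort(unique(df$cluster)) + 1L],
                  sort(unique(df$cluster)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, name = "cluster") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a training history
#'
#' @param object an `imclust_fit`.
#' @param ... unused.
#' @return A ggplot object of loss components and mutual information by epoch.
#' @export
autoplot.imclust_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D embedding coloured by cluster
#'
#' @param coords `N x 2` matrix from [embed_2d()].
#' @param labels integer cluster ids (0-based).
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, labels) {
  df <- tibble(x = coords[, 1], y = coords[, 2], cluster = factor(labels))
  k <- length(levels(df$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = cluster_palette(k)) +
    ggplot2::theme_minimal()
}

#' Plot a validity table across cluster sets
#'
#' @param table long validity tibble (`dataset`, `cluster_set`, `index`,
#'   `value`).
#' @return A ggplot object, one facet per index.
#' @export
plot_validity <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$cluster_set, y = .data$value,
                                      colour = .data$dataset)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::theme_minimal()
}
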
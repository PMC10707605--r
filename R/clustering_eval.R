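#' Internal cluster-validity indices
#'
#' Six classical internal indices score a clustering from the data alone.
#' All use Euclidean distance; a centroid is the arithmetic mean of its
#' members.  Each index carries an optimization direction (see
#' [index_directions()]): for `min` indices smaller is better, for `max`
#' indices larger is better.  All indices require `K >= 2` and no empty
#' cluster, and error on their degenerate cases (zero within-scatter, zero
#' centroid separation, singleton-only clusters).
#'
#' @param x `N x D` numeric feature matrix.
#' @param labels integer vector of 0-based cluster ids covering `[0, K)`.
#' @param soft optional `N x K` row-stochastic membership matrix; when given
#'   to [xie_beni()], the fuzzy variant with squared memberships is used.
#' @name validity_indices
NULL

check_clustered <- function(x, labels) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) abort("`labels` length must match rows of `x`")
  labels <- as.integer(labels)
  k <- max(labels) + 1L
  if (k < 2L) abort("need at least 2 clusters")
  tab <- tabulate(labels + 1L, nbins = k)
  if (any(tab == 0L)) abort("every cluster id in [0, K) must be non-empty")
  list(x = x, labels = labels, k = k, sizes = tab)
}

cluster_centroids <- function(x, labels, k) {
  v <- vapply(seq_len(k) - 1L, function(c)
    colMeans(x[labels == c, , drop = FALSE]), numeric(ncol(x)))
  if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)  # keep K x D for D = 1
}

scatter_sums <- function(x, labels, k) {
  v <- cluster_centroids(x, labels, k)
  g <- colMeans(x)
  ssw <- 0
  for (c in seq_len(k) - 1L) {
    xc <- x[labels == c, , drop = FALSE]
    ssw <- ssw + sum(sweep(xc, 2, v[c + 1L, ])^2)
  }
  sizes <- tabulate(labels + 1L, nbins = k)
  ssb <- sum(sizes * rowSums(sweep(v, 2, g)^2))
  list(ssw = ssw, ssb = ssb, centroids = v)
}

#' @rdname validity_indices
#' @return `xie_beni()`: compactness over separation,
#'   `sum_j ||x_j - v_c(j)||^2 / (N * min_{i != k} ||v_i - v_k||^2)`
#'   (crisp; with `soft`, squared memberships weight both numerator and
#'   centroids).  Lower is better.
#' @export
xie_beni <- function(x, labels, soft = NULL) {
  cp <- check_clustered(x, labels)
  if (is.null(soft)) {
    sc <- scatter_sums(cp$x, cp$labels, cp$k)
    compact <- sc$ssw
    v <- sc$centroids
  } else {
    u2 <- soft^2
    v <- vapply(seq_len(cp$k), function(c)
      colSums(cp$x * u2[, c]) / sum(u2[, c]), numeric(ncol(cp$x)))
    v <- if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)
    compact <- sum(vapply(seq_len(cp$k), function(c)
      sum(u2[, c] * rowSums(sweep(cp$x, 2, v[c, ])^2)), numeric(1)))
  }
  dv <- as.matrix(stats::dist(v))^2
  sep <- min(dv[upper.tri(dv)])
  if (sep <= 0) abort("coincident centroids: Xie-Beni separation is zero")
  compact / (nrow(cp$x) * sep)
}

#' @rdname validity_indices
#' @return `calinski_harabasz()`: `(SSB / (K - 1)) / (SSW / (N - K))`.
#'   Higher is better.
#' @export
calinski_harabasz <- function(x, labels) {
  cp <- check_clustered(x, labels)
  sc <- scatter_sums(cp$x, cp$labels, cp$k)
  if (sc$ssw <= 0) abort("zero within-cluster scatter: index is unbounded")
  (sc$ssb / (cp$k - 1)) / (sc$ssw / (nrow(cp$x) - cp$k))
}

# Logical mask over pairs in the order `as.vector(dist(x))` uses
# (lower triangle, column-major): TRUE where both points share a cluster.
within_pair_mask <- function(labels) {
  same <- outer(labels, labels, "==")
  same[lower.tri(same)]
}

#' @rdname validity_indices
#' @return `c_index()`: `(S - S_min) / (S_max - S_min)` where `S` is the sum
#'   of within-cluster pair distances and `S_min` / `S_max` sum the same
#'   number of globally smallest / largest pairwise distances; in `[0, 1]`,
#'   lower is better.
#' @export
c_index <- function(x, labels) {
  cp <- check_clustered(x, labels)
  dv <- as.vector(stats::dist(cp$x))
  within <- within_pair_mask(cp$labels)
  nw <- sum(within)
  if (nw == 0L) abort("no within-cluster pairs (all clusters are singletons)")
  s <- sum(dv[within])
  ds <- sort(dv)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[length(ds) - seq_len(nw) + 1L])
  if (smax - smin <= 0) abort("all pairwise distances are equal")
  (s - smin) / (smax - smin)
}

#' @rdname validity_indices
#' @param base base of the logarithm (default natural).
#' @return `hartigan()`: `log(SSB / SSW)`; higher is better, may be negative.
#' @export
hartigan <- function(x, labels, base = exp(1)) {
  cp <- check_clustered(x, labels)
  sc <- scatter_sums(cp$x, cp$labels, cp$k)
  if (sc$ssw <= 0) abort("zero within-cluster scatter: index diverges")
  if (sc$ssb <= 0) abort("zero between-cluster scatter: index diverges")
  log(sc$ssb / sc$ssw, base = base)
}

#' @rdname validity_indices
#' @return `dunn()`: minimum inter-cluster point-pair distance over maximum
#'   intra-cluster point-pair distance.  Higher is better.  (Despite a
#'   common misconception the standard index is not bounded above by 1.)
#' @export
dunn <- function(x, labels) {
  cp <- check_clustered(x, labels)
  dv <- as.vector(stats::dist(cp$x))
  within <- within_pair_mask(cp$labels)
  if (!any(within)) abort("no within-cluster pairs (all clusters are singletons)")
  dmax <- max(dv[within])
  if (dmax <= 0) abort("zero intra-cluster diameter")
  min(dv[!within]) / dmax
}

#' @rdname validity_indices
#' @return `mclain_rao()`: mean within-cluster pair distance over mean
#'   between-cluster pair distance.  Lower is better.
#' @export
mclain_rao <- function(x, labels) {
  cp <- check_clustered(x, labels)
  dv <- as.vector(stats::dist(cp$x))
  within <- within_pair_mask(cp$labels)
  if (!any(within)) abort("no within-cluster pairs")
  mean(dv[within]) / mean(dv[!within])
}

#' Optimization direction of each validity index
#'
#' @return Named character vector mapping index name to `"min"` or `"max"`.
#' @export
index_directions <- function() {
  c(xie_beni = "min", calinski_harabasz = "max", c_index = "min",
    hartigan = "max", dunn = "max", mclain_rao = "min")
}

#' Score one clustering with all six validity indices
#'
#' @inheritParams validity_indices
#' @param cluster_set the candidate cluster count this clustering used
#'   (recorded in the output).
#' @param dataset tag naming the dataset/configuration (recorded).
#' @return A six-row tibble: `dataset`, `cluster_set`, `index`, `value`.
#' @export
compute_validity <- function(x, labels, soft = NULL,
                             cluster_set = max(labels) + 1L,
                             dataset = "default") {
  vals <- c(
    xie_beni = xie_beni(x, labels, soft = soft),
    calinski_harabasz = calinski_harabasz(x, labels),
    c_index = c_index(x, labels),
    hartigan = hartigan(x, labels),
    dunn = dunn(x, labels),
    mclain_rao = mclain_rao(x, labels)
  )
  tibble(dataset = dataset, cluster_set = as.integer(cluster_set),
         index = names(vals), value = unname(vals))
}

#' Select the optimal cluster count per index column
#'
#' For every `(dataset, index)` column the optimal cluster set is the
#' argmin (`min`-direction indices) or argmax (`max`-direction); ties break
#' toward the smallest cluster count and are flagged.
#'
#' @param table a long validity table with columns `dataset`, `cluster_set`,
#'   `index`, `value` (as produced by [compute_validity()] or
#'   [read_validity_table()]).
#' @return A tibble with one row per `(dataset, index)`: `optimal_k`, `tied`.
#' @export
select_optimal <- function(table) {
  dirs <- index_directions()
  bad <- setdiff(unique(table$index), names(dirs))
  if (length(bad))
    abort(sprintf("unknown index name(s): %s", paste(bad, collapse = ", ")))
  table |>
    group_by(.data$dataset, .data$index) |>
    summarise(
      optimal_k = {
        v <- if (dirs[[.data$index[1]]] == "min") .data$value else -.data$value
        .data$cluster_set[order(v, .data$cluster_set)][1]
      },
      tied = {
        v <- if (dirs[[.data$index[1]]] == "min") .data$value else -.data$value
        sum(v == min(v)) > 1L
      },
      .groups = "drop"
    )
}

#' Aggregate per-index optima by vote
#'
#' @param optima output of [select_optimal()].
#' @return A `validity_vote`: list with `mode_k` (winning cluster count,
#'   smallest on ties), `n_votes`, `tied` (logical) and `votes`
#'   (tibble of `optimal_k`, `n`; counts sum to the number of columns).
#' @export
vote_optimal <- function(optima) {
  votes <- optima |> count(.data$optimal_k) |> arrange(dplyr::desc(.data$n),
                                                       .data$optimal_k)
  structure(list(mode_k = votes$optimal_k[1], n_votes = votes$n[1],
                 tied = sum(votes$n == votes$n[1]) > 1L, votes = votes),
            class = "validity_vote")
}

#' @export
print.validity_vote <- function(x, ...) {
  cat(sprintf("<validity_vote> optimal K = %d with %d of %d votes%s\n",
              x$mode_k, x$n_votes, sum(x$votes$n),
              if (x$tied) " (tied)" else ""))
  invisible(x)
}

#' Agreement between two labelings
#'
#' Adjusted Rand index and normalized mutual information (arithmetic-mean
#' normalization); both invariant to cluster relabeling.
#'
#' @param labels,truth integer label vectors of equal length.
#' @return A one-row tibble with `ari` and `nmi`.
#' @export
agreement <- function(labels, truth) {
  if (length(labels) != length(truth)) abort("label vectors differ in length")
  tibble(ari = mclust::adjustedRandIndex(labels, truth),
         nmi = nmi(labels, truth))
}

#' Normalized mutual information between two labelings
#'
#' `I(U; V) / mean(H(U), H(V))` computed from the contingency table, in
#' `[0, 1]`; 0 for independent labelings (in expectation), 1 for labelings
#' identical up to renaming.
#'
#' @inheritParams agreement
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(labels, truth) {
  tab <- table(labels, truth)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  hu <- entropy(pi); hv <- entropy(pj)
  if (hu == 0 && hv == 0) return(1)
  denom <- (hu + hv) / 2
  if (denom == 0) return(0)
  mi / denom
}

#' Read / write a long-format validity table
#'
#' CSV with columns `dataset`, `cluster_set`, `index`, `value`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_validity_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("dataset", "cluster_set", "index", "value")
  if (!all(need %in% names(tb)))
    abort(sprintf("validity table needs columns: %s",
                  paste(need, collapse = ", ")))
  tb
}

#' @rdname read_validity_table
#' @param table a long validity table.
#' @export
write_validity_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Reference validity-index grid for the KPC multi-stain patch datasets
#'
#' The published grid of six internal validity indices over candidate
#' cluster counts 8-18 for the two KPC patch datasets (128x128 and 64x64
#' pixels), shipped as a plain-text fixture.  Feeding it through
#' [select_optimal()] and [vote_optimal()] reproduces the selection of 14
#' clusters with 6 of 12 votes.
#'
#' @return A long-format validity tibble (132 rows).
#' @export
reference_validity_grid <- function() {
  read_validity_table(system.file("extdata", "kpc_validity_indices.csv",
                                  package = "stainclust", mustWork = TRUE))
}
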
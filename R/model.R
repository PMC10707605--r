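#' Configuration of the convolutional autoencoder
#'
#' The network has three parts.  The *encoder* maps a `(side, side,
#' in_channels)` patch through a stride-1 stem convolution and a chain of
#' stride-2 convolutions (channel plan `channel_plan`, then `upper_dim`),
#' each followed by a leaky rectifier, and global-average-pools to the
#' upper latent vector of length `upper_dim`.  The *classifier* reduces the
#' upper latent space through a hidden fully connected layer to `n_clusters`
#' softmax probabilities (the lower latent space / soft cluster assignment).
#' The *decoder* maps the concatenation of upper and lower latent features
#' through a fully connected layer and mirrored transposed convolutions back
#' to the input size, ending in a sigmoid so reconstructions live in (0, 1).
#'
#' Inputs larger than `input_rescale` (when set) are bilinearly downscaled
#' before the encoder, keeping network depth constant across patch sizes;
#' the reconstruction target is then the rescaled input.
#'
#' @param n_clusters number of clusters `n_c` (>= 2).
#' @param in_channels input channels (default 15 = 5 stains x RGB).
#' @param input_size side length of incoming patches.
#' @param input_rescale optional side length the encoder works at; `NULL`
#'   means no rescaling.  The working side must be divisible by
#'   `2^(length(channel_plan))`.
#' @param channel_plan channel widths of the stride-2 convolution chain
#'   (default `c(45, 128, 128)`; the full-scale plan 15 -> 45 -> 128 ->
#'   196 -> n_c arises with the default `upper_dim`).
#' @param upper_dim upper latent dimension `D` (default 196; must be >=
#'   `n_clusters`).
#' @param classifier_hidden hidden width of the classifier (default 128).
#' @param leaky_slope negative slope of the leaky rectifier (default 0.1).
#' @return A `model_config` list.
#' @export
model_config <- function(n_clusters, in_channels = 15L, input_size = 64L,
                         input_rescale = NULL, channel_plan = c(45L, 128L, 128L),
                         upper_dim = 196L, classifier_hidden = 128L,
                         leaky_slope = 0.1) {
  if (n_clusters < 2) abort("`n_clusters` must be >= 2")
  if (upper_dim < n_clusters) abort("`upper_dim` must be >= `n_clusters`")
  side <- if (is.null(input_rescale)) input_size else input_rescale
  halvings <- length(channel_plan)
  if (side %% 2^halvings != 0 || side %/% 2^halvings < 1)
    abort(sprintf("working side %d not divisible by 2^%d", side, halvings))
  structure(list(n_clusters = as.integer(n_clusters),
                 in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 input_rescale = if (is.null(input_rescale)) NULL
                                 else as.integer(input_rescale),
                 channel_plan = as.integer(channel_plan),
                 upper_dim = as.integer(upper_dim),
                 classifier_hidden = as.integer(classifier_hidden),
                 leaky_slope = leaky_slope),
            class = "model_config")
}

#' Desk-scale reduced model configuration
#'
#' A small instance of the same architecture for laptop-scale experiments
#' and the synthetic-recovery benchmarks: 32 px patches worked at 8 px,
#' channel plan `c(8, 16)`, 32-dimensional upper latent space.
#'
#' @inheritParams model_config
#' @return A `model_config`.
#' @export
model_config_reduced <- function(n_clusters, in_channels = 15L,
                                 input_size = 32L) {
  model_config(n_clusters, in_channels = in_channels,
               input_size = input_size, input_rescale = 8L,
               channel_plan = c(8L, 16L), upper_dim = 32L,
               classifier_hidden = 32L)
}

# ---- layer primitives -------------------------------------------------------

new_conv <- function(cin, cout, k, stride, pad) {
  sd <- sqrt(2 / (k * k * cin))
  list(type = "conv", w = array(rnorm(k * k * cin * cout, 0, sd),
                                dim = c(k, k, cin, cout)),
       b = numeric(cout), stride = stride, pad = pad)
}

new_convt <- function(cin, cout, k, stride, pad) {
  sd <- sqrt(2 / (k * k * cin))
  list(type = "convt", w = array(rnorm(k * k * cout * cin, 0, sd),
                                 dim = c(k, k, cout, cin)),
       b = numeric(cout), stride = stride, pad = pad)
}

new_dense <- function(din, dout) {
  sd <- sqrt(2 / din)
  list(type = "dense", w = matrix(rnorm(din * dout, 0, sd), din, dout),
       b = numeric(dout))
}

layer_forward <- function(layer, x, slope) {
  switch(layer$type,
    conv = cpp_conv2d_fwd(x, layer$w, layer$b, layer$stride, layer$pad),
    convt = cpp_convt2d_fwd(x, layer$w, layer$b, layer$stride, layer$pad),
    dense = sweep(x %*% layer$w, 2, layer$b, "+"),
    lrelu = { y <- x; neg <- x < 0; y[neg] <- slope * x[neg]; y },
    sigmoid = 1 / (1 + exp(-x)),
    softmax = { m <- x - apply(x, 1, max); e <- exp(m); e / rowSums(e) },
    gap = {
      d <- dim(x)
      m <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
      t(m)
    },
    reshape = array(as.vector(t(x)), dim = c(layer$shape, nrow(x))),
    abort(sprintf("unknown layer type %s", layer$type))
  )
}

layer_backward <- function(layer, x, dy, slope) {
  switch(layer$type,
    conv = cpp_conv2d_bwd(x, layer$w, dy, layer$stride, layer$pad),
    convt = cpp_convt2d_bwd(x, layer$w, dy, layer$stride, layer$pad),
    dense = list(dx = dy %*% t(layer$w), dw = t(x) %*% dy, db = colSums(dy)),
    lrelu = { g <- dy; neg <- x < 0; g[neg] <- slope * dy[neg]; list(dx = g) },
    sigmoid = { y <- 1 / (1 + exp(-x)); list(dx = dy * y * (1 - y)) },
    softmax = {
      m <- x - apply(x, 1, max); e <- exp(m); p <- e / rowSums(e)
      list(dx = p * (dy - rowSums(dy * p)))
    },
    gap = {
      d <- dim(x)
      scale <- 1 / (d[1] * d[2])
      dx <- array(rep(as.vector(t(dy)) * scale, each = d[1] * d[2]), dim = d)
      list(dx = dx)
    },
    reshape = {
      n <- dim(dy)[length(dim(dy))]
      list(dx = t(matrix(dy, prod(layer$shape), n)))
    },
    abort(sprintf("unknown layer type %s", layer$type))
  )
}

net_forward <- function(layers, x, slope) {
  inputs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    inputs[[i]] <- x
    x <- layer_forward(layers[[i]], x, slope)
  }
  list(out = x, inputs = inputs)
}

# `skip_input_grad` skips the (unused) gradient w.r.t. the raw input of the
# first layer — a worthwhile saving when that layer is the full-resolution
# stem convolution.
net_backward <- function(layers, inputs, dout, slope, skip_input_grad = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (skip_input_grad && i == 1L && layers[[i]]$type == "conv") {
      bk <- cpp_conv2d_bwd_nodx(inputs[[i]], layers[[i]]$w, dout,
                                layers[[i]]$stride, layers[[i]]$pad)
      grads[[i]] <- list(dw = bk$dw, db = bk$db)
      dout <- NULL
      break
    }
    bk <- layer_backward(layers[[i]], inputs[[i]], dout, slope)
    if (!is.null(bk$dw)) grads[[i]] <- list(dw = bk$dw, db = bk$db)
    dout <- bk$dx
  }
  list(dx = dout, grads = grads)
}

# ---- network construction ---------------------------------------------------

#' Initialize a network state
#'
#' Weights use fan-in-scaled Gaussian initialization under a fixed seed;
#' biases start at zero.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed.
#' @return An `imclust_network` (all learnable parameters plus the config).
#' @export
init_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  side <- if (is.null(config$input_rescale)) config$input_size
          else config$input_rescale
  plan <- config$channel_plan
  f <- side %/% 2^length(plan)
  with_seed(seed, {
    enc <- list(new_conv(config$in_channels, plan[1], 3L, 1L, 1L),
                list(type = "lrelu"))
    chain <- c(plan, config$upper_dim)
    for (i in seq_len(length(chain) - 1L)) {
      enc <- c(enc, list(new_conv(chain[i], chain[i + 1L], 4L, 2L, 1L),
                         list(type = "lrelu")))
    }
    enc <- c(enc, list(list(type = "gap")))

    cls <- list(new_dense(config$upper_dim, config$classifier_hidden),
                list(type = "lrelu"),
                new_dense(config$classifier_hidden, config$n_clusters),
                list(type = "softmax"))

    dec <- list(new_dense(config$upper_dim + config$n_clusters,
                          f * f * plan[length(plan)]),
                list(type = "lrelu"),
                list(type = "reshape", shape = c(f, f, plan[length(plan)])))
    rev_chain <- rev(plan)
    if (length(rev_chain) > 1L) {
      for (i in seq_len(length(rev_chain) - 1L)) {
        dec <- c(dec, list(new_convt(rev_chain[i], rev_chain[i + 1L], 4L, 2L, 1L),
                           list(type = "lrelu")))
      }
    }
    dec <- c(dec, list(new_convt(plan[1], plan[1], 4L, 2L, 1L),
                       list(type = "lrelu"),
                       new_conv(plan[1], config$in_channels, 3L, 1L, 1L),
                       list(type = "sigmoid")))

    structure(list(config = config, encoder = enc, classifier = cls,
                   decoder = dec, seed = as.integer(seed)),
              class = "imclust_network")
  })
}

#' @export
print.imclust_network <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(c(x$encoder, x$classifier, x$decoder), function(l)
    length(l$w) + length(l$b), numeric(1)))
  cat(sprintf(
    "<imclust_network> %d clusters, D=%d, %s channels, %d parameters\n",
    cfg$n_clusters, cfg$upper_dim,
    paste(c(cfg$in_channels, cfg$channel_plan, cfg$upper_dim), collapse = "-"),
    np))
  invisible(x)
}

# Coerce patch input to the (side, side, C, N) array the encoder works on.
encoder_input <- function(x, config) {
  if (inherits(x, "stain_patchset")) x <- x$data
  d <- dim(x)
  if (length(d) != 4L) abort("input must be a (H, W, C, N) array or patch set")
  if (d[3] != config$in_channels)
    abort(sprintf("input has %d channels, model expects %d", d[3],
                  config$in_channels))
  side <- if (is.null(config$input_rescale)) config$input_size
          else config$input_rescale
  if (d[1] != side || d[2] != side) {
    if (is.null(config$input_rescale) ||
        d[1] != config$input_size || d[2] != config$input_size)
      abort(sprintf("input is %dx%d px, model expects %dx%d", d[1], d[2],
                    config$input_size, config$input_size))
    x <- cpp_resize_bilinear(x, side, side)
  }
  x
}

#' Encode patches into the upper latent space
#'
#' @param patches a `stain_patchset` or `(H, W, C, N)` array.
#' @param state an `imclust_network`.
#' @return `N x upper_dim` embedding matrix.
#' @export
encode <- function(patches, state) {
  stopifnot(inherits(state, "imclust_network"))
  x <- encoder_input(patches, state$config)
  net_forward(state$encoder, x, state$config$leaky_slope)$out
}

#' Soft cluster assignment from upper latent features
#'
#' @param upper `N x upper_dim` embedding matrix.
#' @param state an `imclust_network`.
#' @return `N x n_clusters` row-stochastic soft-assignment matrix.
#' @export
classify <- function(upper, state) {
  stopifnot(inherits(state, "imclust_network"))
  if (ncol(upper) != state$config$upper_dim)
    abort(sprintf("embedding has %d columns, model expects %d", ncol(upper),
                  state$config$upper_dim))
  net_forward(state$classifier, upper, state$config$leaky_slope)$out
}

#' Reconstruct patches from concatenated latent features
#'
#' @param upper `N x upper_dim` embedding matrix.
#' @param lower `N x n_clusters` soft-assignment matrix.
#' @param state an `imclust_network`.
#' @return `(side, side, C, N)` reconstruction array with values in (0, 1),
#'   where `side` is the encoder working size.
#' @export
decode <- function(upper, lower, state) {
  stopifnot(inherits(state, "imclust_network"))
  if (nrow(upper) != nrow(lower)) abort("`upper` and `lower` row counts differ")
  z <- cbind(upper, lower)
  net_forward(state$decoder, z, state$config$leaky_slope)$out
}

# ---- persistence ------------------------------------------------------------

#' Save a network state to disk
#'
#' The full state (weights + config) is serialized with `saveRDS()`; a JSON
#' sidecar `<path>.json` records the architecture for inspection.
#'
#' @param state an `imclust_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_network <- function(state, path) {
  saveRDS(state, path)
  cfg <- state$config
  jsonlite::write_json(
    list(n_clusters = cfg$n_clusters, in_channels = cfg$in_channels,
         input_size = cfg$input_size,
         input_rescale = cfg$input_rescale,
         channel_plan = cfg$channel_plan, upper_dim = cfg$upper_dim,
         classifier_hidden = cfg$classifier_hidden,
         leaky_slope = cfg$leaky_slope, seed = state$seed),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a network state saved by [save_network()]
#'
#' @param path file path.
#' @return An `imclust_network`, bit-identical to the saved state.
#' @export
load_network <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "imclust_network"))
  state
}
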
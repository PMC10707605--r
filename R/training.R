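#' Training configuration
#'
#' Defaults follow the full-scale recipe: batches of 100 patches, Adadelta
#' with learning rate 0.003, loss weights `(0.1, 0.03, 0.03)`, 3000-4000
#' epochs.  The desk-scale profile (see [pipeline_config()]) uses the same
#' objective with fewer epochs and a unit learning rate so that runs finish
#' in minutes on one CPU.
#'
#' @param n_clusters number of clusters `n_c`.
#' @param epochs number of passes over the dataset (>= 1).
#' @param batch_size mini-batch size (>= 2; the marginal entropy is
#'   estimated per batch and needs more than one sample).
#' @param learning_rate Adadelta step multiplier.
#' @param rho Adadelta decay of the squared-gradient / squared-update
#'   accumulators.
#' @param epsilon Adadelta numerical floor.
#' @param weights a [loss_weights()].
#' @param affine an [affine_ranges()] for the consistency branch.
#' @param seed integer seed fixing initialization, shuffling and
#'   augmentation.
#' @param checkpoint_every optional epoch interval for checkpoints.
#' @param checkpoint_dir directory for checkpoints (created on demand).
#' @return A `train_config` list.
#' @export
train_config <- function(n_clusters, epochs = 300L, batch_size = 100L,
                         learning_rate = 0.003, rho = 0.95, epsilon = 1e-6,
                         weights = loss_weights(), affine = affine_ranges(),
                         seed = 1L, checkpoint_every = NULL,
                         checkpoint_dir = NULL) {
  if (epochs < 1) abort("`epochs` must be >= 1")
  if (batch_size < 2) abort("`batch_size` must be >= 2")
  structure(list(n_clusters = as.integer(n_clusters),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 weights = weights, affine = affine, seed = as.integer(seed),
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# One combined forward/backward pass over a batch.  `x` and `xa` are
# encoder-sized arrays (originals and affine copies).  Returns the loss
# breakdown and parameter gradients for the three sub-networks.
imclust_step <- function(state, x, xa, weights) {
  slope <- state$config$leaky_slope
  eps <- .ENT_EPS
  n <- dim(x)[4]
  D <- state$config$upper_dim

  enc_o <- net_forward(state$encoder, x, slope)
  cls_o <- net_forward(state$classifier, enc_o$out, slope)
  enc_a <- net_forward(state$encoder, xa, slope)
  cls_a <- net_forward(state$classifier, enc_a$out, slope)
  P <- cls_o$out
  Q <- cls_a$out
  dec_o <- net_forward(state$decoder, cbind(enc_o$out, P), slope)
  xhat <- dec_o$out

  m <- colMeans(P)
  recon <- mean((x - xhat)^2)
  hy <- entropy(m / sum(m))
  hyx <- mean(-rowSums(P * log(pmax(P, eps))))
  Pf <- pmax(P, eps); Qf <- pmax(Q, eps)
  kl <- mean(rowSums(P * (log(Pf) - log(Qf))))
  breakdown <- total_loss(recon, hy, hyx, kl, weights)

  # reconstruction head
  dxhat <- 2 * (xhat - x) / length(x)
  dec_b <- net_backward(state$decoder, dec_o$inputs, dxhat, slope)
  dz <- dec_b$dx
  dE <- dz[, seq_len(D), drop = FALSE]
  dP <- dz[, D + seq_len(state$config$n_clusters), drop = FALSE]

  # information-maximization and consistency heads (gradients w.r.t. P, Q)
  dP <- dP + weights$lambda_me *
    matrix(log(pmax(m, eps)) + 1, n, length(m), byrow = TRUE) / n
  dP <- dP - weights$lambda_ce * (log(Pf) + 1) / n
  dP <- dP + weights$lambda_af * (log(Pf) - log(Qf) + 1) / n
  dQ <- -weights$lambda_af * (P / Qf) / n

  cls_b <- net_backward(state$classifier, cls_o$inputs, dP, slope)
  enc_b <- net_backward(state$encoder, enc_o$inputs, dE + cls_b$dx, slope,
                        skip_input_grad = TRUE)
  cls_ab <- net_backward(state$classifier, cls_a$inputs, dQ, slope)
  enc_ab <- net_backward(state$encoder, enc_a$inputs, cls_ab$dx, slope,
                         skip_input_grad = TRUE)

  add_grads <- function(a, b) {
    for (i in seq_along(a)) {
      if (!is.null(a[[i]])) {
        a[[i]]$dw <- a[[i]]$dw + b[[i]]$dw
        a[[i]]$db <- a[[i]]$db + b[[i]]$db
      }
    }
    a
  }
  list(breakdown = breakdown,
       grads = list(encoder = add_grads(enc_b$grads, enc_ab$grads),
                    classifier = add_grads(cls_b$grads, cls_ab$grads),
                    decoder = dec_b$grads))
}

adadelta_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$w)) return(NULL)
    list(eg_w = array(0, dim = dim(l$w)), ed_w = array(0, dim = dim(l$w)),
         eg_b = numeric(length(l$b)), ed_b = numeric(length(l$b)))
  })
}

adadelta_update <- function(layers, grads, opt, lr, rho, eps) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    o <- opt[[i]]
    o$eg_w <- rho * o$eg_w + (1 - rho) * g$dw^2
    dw <- -sqrt((o$ed_w + eps) / (o$eg_w + eps)) * g$dw
    o$ed_w <- rho * o$ed_w + (1 - rho) * dw^2
    layers[[i]]$w <- layers[[i]]$w + lr * dw
    o$eg_b <- rho * o$eg_b + (1 - rho) * g$db^2
    db <- -sqrt((o$ed_b + eps) / (o$eg_b + eps)) * g$db
    o$ed_b <- rho * o$ed_b + (1 - rho) * db^2
    layers[[i]]$b <- layers[[i]]$b + lr * db
    opt[[i]] <- o
  }
  list(layers = layers, opt = opt)
}

#' Train the information-maximization clustering network
#'
#' Per batch, originals and one affine-transformed copy per sample are both
#' passed through the encoder and classifier; the combined loss
#' (reconstruction MSE of the originals, weighted marginal/conditional
#' entropies of the original assignments, and the KL consistency between the
#' two assignment sets) is backpropagated and the parameters stepped with
#' Adadelta.  The dataset is reshuffled every epoch; a final short batch is
#' dropped (the per-batch marginal entropy is unstable on tiny remainders)
#' unless the dataset is smaller than one batch.
#'
#' @param dataset a non-empty `stain_patchset`.
#' @param config a [train_config()].
#' @param model optional [model_config()]; defaults to
#'   [model_config_reduced()] sized to the dataset.
#' @param verbose print a progress line every `verbose` epochs (0 = silent).
#' @return An `imclust_fit`: list with `state` (the trained
#'   `imclust_network`) and `history` (one-row-per-epoch tibble of loss
#'   components and mutual information).
#' @export
train_imclust <- function(dataset, config, model = NULL, verbose = 0L) {
  stopifnot(inherits(dataset, "stain_patchset"),
            inherits(config, "train_config"))
  d <- dim(dataset$data)
  if (d[4] == 0L) abort("`dataset` is empty")
  if (is.null(model))
    model <- model_config_reduced(config$n_clusters, in_channels = d[3],
                                  input_size = d[1])
  if (model$in_channels != d[3])
    abort(sprintf("dataset has %d channels, model expects %d", d[3],
                  model$in_channels))
  state <- init_network(model, seed = config$seed)
  opt <- list(encoder = adadelta_init(state$encoder),
              classifier = adadelta_init(state$classifier),
              decoder = adadelta_init(state$decoder))
  n <- d[4]
  bs <- min(config$batch_size, n)
  nb <- max(1L, n %/% bs)
  history <- vector("list", config$epochs)
  # resize to the encoder working size once; augmentation is applied at
  # that working resolution (bilinear warps of [0,1] data stay in [0,1])
  xall <- encoder_input(dataset$data, model)
  side <- dim(xall)[1]
  rng <- config$affine

  with_seed(config$seed %% 1000000000L + 17L, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      acc <- NULL
      for (b in seq_len(nb)) {
        idx <- perm[(b - 1L) * bs + seq_len(bs)]
        x <- xall[, , , idx, drop = FALSE]
        params <- rbind(
          runif(bs, rng$angle_deg[1], rng$angle_deg[2]) * pi / 180,
          runif(bs, rng$shift_frac[1], rng$shift_frac[2]) * side,
          runif(bs, rng$shift_frac[1], rng$shift_frac[2]) * side,
          runif(bs, rng$scale[1], rng$scale[2]))
        xa <- cpp_affine_warp(x, params)
        step <- imclust_step(state, x, xa, config$weights)
        if (!is.finite(step$breakdown$total))
          abort(sprintf("non-finite loss at epoch %d batch %d: %s", epoch, b,
                        paste(utils::capture.output(step$breakdown), collapse = " ")))
        upd <- adadelta_update(state$encoder, step$grads$encoder,
                               opt$encoder, config$learning_rate, config$rho,
                               config$epsilon)
        state$encoder <- upd$layers; opt$encoder <- upd$opt
        upd <- adadelta_update(state$classifier, step$grads$classifier,
                               opt$classifier, config$learning_rate,
                               config$rho, config$epsilon)
        state$classifier <- upd$layers; opt$classifier <- upd$opt
        upd <- adadelta_update(state$decoder, step$grads$decoder,
                               opt$decoder, config$learning_rate, config$rho,
                               config$epsilon)
        state$decoder <- upd$layers; opt$decoder <- upd$opt
        acc <- if (is.null(acc)) step$breakdown else acc + step$breakdown
      }
      history[[epoch]] <- tibble::as_tibble(as.list(unlist(acc / nb)))
      history[[epoch]]$epoch <- epoch
      if (verbose > 0 && epoch %% verbose == 0)
        message(sprintf("epoch %4d  total %.5f  MI %.4f", epoch,
                        history[[epoch]]$total, history[[epoch]]$mutual_info))
      if (!is.null(config$checkpoint_every) &&
          epoch %% config$checkpoint_every == 0L &&
          !is.null(config$checkpoint_dir)) {
        dir.create(config$checkpoint_dir, showWarnings = FALSE,
                   recursive = TRUE)
        save_network(state, file.path(config$checkpoint_dir,
                                      sprintf("epoch%04d.rds", epoch)))
      }
    }
  })
  history <- dplyr::bind_rows(history)
  history <- history[, c("epoch", "recon", "marginal_entropy",
                         "conditional_entropy", "affine_kl", "mutual_info",
                         "total")]
  structure(list(state = state, history = history, config = config),
            class = "imclust_fit")
}

#' @export
print.imclust_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<imclust_fit> %d clusters, %d epochs; final total %.5f, MI %.4f nats\n",
    x$state$config$n_clusters, nrow(x$history), last$total, last$mutual_info))
  invisible(x)
}

# Row argmax with ties broken toward the lowest cluster index; 0-based.
hard_assign <- function(soft) max.col(soft, ties.method = "first") - 1L

#' Hard cluster assignment for a dataset
#'
#' Labels are the per-row argmax of the soft assignment; ties break toward
#' the lowest cluster index.  Labels are 0-based, in `[0, n_clusters)`.
#'
#' @param state an `imclust_network` (or an `imclust_fit`).
#' @param dataset a `stain_patchset`.
#' @return A `cluster_assignment`: list with `labels` (integer vector) and
#'   `soft` (`N x n_clusters` matrix).
#' @export
assign_clusters <- function(state, dataset) {
  if (inherits(state, "imclust_fit")) state <- state$state
  soft <- classify(encode(dataset, state), state)
  structure(list(labels = hard_assign(soft), soft = soft),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d patches over %d clusters\n",
              length(x$labels), ncol(x$soft)))
  invisible(x)
}

#' @export
as_tibble.cluster_assignment <- function(x, ...) {
  tibble(patch = seq_along(x$labels), label = x$labels,
         confidence = apply(x$soft, 1, max))
}

#' Per-epoch training history
#'
#' @param x an `imclust_fit`.
#' @param ... unused.
#' @return The history tibble (`epoch`, loss components, `mutual_info`,
#'   `total`).
#' @export
tidy.imclust_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x an `imclust_fit`.
#' @param ... unused.
#' @return A one-row tibble: cluster count, epochs, final loss components
#'   and the gain in mutual information over training.
#' @export
glance.imclust_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  tibble(n_clusters = x$state$config$n_clusters, epochs = nrow(h),
         final_total = last$total, final_mutual_info = last$mutual_info,
         mi_gain = last$mutual_info - h$mutual_info[1])
}
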
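#' Loss weights for the combined objective
#'
#' The total training objective is
#' \deqn{L = R_L - (\lambda_{ME} H(Y) - \lambda_{CE} H(Y|X)) + \lambda_{AF} L_{AF}}
#' where \eqn{R_L} is the reconstruction mean-squared error, \eqn{H(Y)} the
#' marginal assignment entropy, \eqn{H(Y|X)} the conditional assignment
#' entropy and \eqn{L_{AF}} the affine-consistency KL penalty.  Maximizing
#' \eqn{\lambda_{ME} H(Y) - \lambda_{CE} H(Y|X)} maximizes (a weighted form
#' of) the mutual information between patches and cluster assignments.
#'
#' @param lambda_me weight of the marginal entropy (default 0.1).
#' @param lambda_ce weight of the conditional entropy (default 0.03).
#' @param lambda_af weight of the affine KL penalty (default 0.03).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_me = 0.1, lambda_ce = 0.03, lambda_af = 0.03) {
  if (lambda_me < 0 || lambda_ce < 0 || lambda_af < 0)
    abort("loss weights must be non-negative")
  structure(list(lambda_me = lambda_me, lambda_ce = lambda_ce,
                 lambda_af = lambda_af), class = "loss_weights")
}

.ENT_EPS <- 1e-12

#' Shannon entropy of a probability vector (nats)
#'
#' `0 * log(0)` is treated as 0; the result lies in `[0, log(length(p))]`.
#'
#' @param p non-negative numeric vector summing to 1 (tolerance 1e-6).
#' @return Entropy in nats.
#' @export
entropy <- function(p) {
  if (any(p < -1e-9)) abort("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) abort("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

check_row_stochastic <- function(p) {
  if (!is.matrix(p) || nrow(p) == 0L) abort("need a non-empty matrix")
  if (any(p < -1e-9)) abort("assignment entries must be non-negative")
  if (any(abs(rowSums(p) - 1) > 1e-6)) abort("rows must sum to 1")
  invisible(p)
}

#' Conditional assignment entropy H(Y|X)
#'
#' Mean of the per-row entropies of a row-stochastic soft-assignment matrix:
#' small when every patch is assigned confidently.
#'
#' @param assignments `N x K` row-stochastic matrix.
#' @return Value in `[0, log K]` nats.
#' @export
conditional_entropy <- function(assignments) {
  check_row_stochastic(assignments)
  q <- pmax(assignments, .ENT_EPS)
  mean(-rowSums(assignments * log(q)))
}

#' Marginal assignment entropy H(Y)
#'
#' Entropy of the column-mean (average assignment) distribution: large when
#' clusters are used evenly across the batch.
#'
#' @inheritParams conditional_entropy
#' @return Value in `[0, log K]` nats.
#' @export
marginal_entropy <- function(assignments) {
  check_row_stochastic(assignments)
  entropy(colMeans(assignments))
}

#' Plug-in mutual information between inputs and cluster assignments
#'
#' `marginal_entropy(p) - conditional_entropy(p)`; non-negative for every
#' row-stochastic matrix by concavity of the entropy function.
#'
#' @inheritParams conditional_entropy
#' @return Mutual information in nats (>= 0 up to rounding).
#' @export
mutual_information <- function(assignments) {
  marginal_entropy(assignments) - conditional_entropy(assignments)
}

#' Reconstruction mean-squared error
#'
#' Mean of squared element-wise differences over all array elements.
#'
#' @param original,reconstructed arrays of identical shape.
#' @return MSE (>= 0).
#' @export
reconstruction_mse <- function(original, reconstructed) {
  if (!identical(dim(original), dim(reconstructed)) ||
      length(original) != length(reconstructed))
    abort("shapes differ")
  mean((original - reconstructed)^2)
}

#' Affine-consistency KL penalty
#'
#' Row-mean of `KL(P_row || Q_row)` between the soft assignments of original
#' patches (`p_original`, the reference) and their affine-transformed copies
#' (`p_transformed`), with epsilon flooring inside the logarithm.  Zero iff
#' the rows agree (up to the floor); always non-negative (Gibbs' inequality).
#'
#' @param p_original,p_transformed `N x K` row-stochastic matrices.
#' @return Mean KL divergence in nats (>= 0).
#' @export
affine_kl <- function(p_original, p_transformed) {
  check_row_stochastic(p_original)
  check_row_stochastic(p_transformed)
  if (!all(dim(p_original) == dim(p_transformed))) abort("shapes differ")
  p <- pmax(p_original, .ENT_EPS)
  q <- pmax(p_transformed, .ENT_EPS)
  mean(rowSums(p_original * (log(p) - log(q))))
}

#' Assemble the combined loss from its components
#'
#' @param recon reconstruction MSE (>= 0).
#' @param marginal marginal entropy H(Y).
#' @param conditional conditional entropy H(Y|X).
#' @param affine affine KL penalty (>= 0).
#' @param weights a [loss_weights()].
#' @return A one-row tibble (`loss_breakdown`): `recon`, `marginal_entropy`,
#'   `conditional_entropy`, `affine_kl`, `mutual_info`, `total`, with
#'   `total = recon - (lambda_me * marginal - lambda_ce * conditional) +
#'   lambda_af * affine`.
#' @export
total_loss <- function(recon, marginal, conditional, affine,
                       weights = loss_weights()) {
  if (recon < 0 || affine < 0)
    abort("`recon` and `affine` must be non-negative")
  if (!all(is.finite(c(recon, marginal, conditional, affine))))
    abort("loss components must be finite")
  total <- recon - (weights$lambda_me * marginal -
                    weights$lambda_ce * conditional) +
    weights$lambda_af * affine
  structure(tibble(recon = recon, marginal_entropy = marginal,
                   conditional_entropy = conditional, affine_kl = affine,
                   mutual_info = marginal - conditional, total = total),
            class = c("loss_breakdown", "tbl_df", "tbl", "data.frame"))
}
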
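#' Model hyperparameters for hyperbolic logistic matrix factorization
#'
#' @param d latent dimension of the hyperbolic space (points live in
#'   ambient dimension d+1).
#' @param c confidence weight assigned to observed interactions
#'   (cells with r = 1); non-interactions keep weight 1.  \code{c >= 1}.
#' @param alpha_U,alpha_V prior precisions for drug and target rows,
#'   equal to 1/(2 sigma^2) of the wrapped-normal prior; >= 0.  A value
#'   of 0 disables the corresponding prior entirely, including its
#'   volume-correction term.
#' @param beta_U,beta_V neighborhood-regularization weights for the
#'   drug-drug and target-target similarity penalties; >= 0.
#' @return an object of class \code{"hmf_params"}.
#' @export
hmf_params <- function(d = 5L, c = 5, alpha_U = 0.1, alpha_V = 0.1,
                       beta_U = 0, beta_V = 0) {
  if (d < 1L) stop("hmf_params: d must be >= 1")
  if (c < 1) stop("hmf_params: c must be >= 1")
  if (alpha_U < 0 || alpha_V < 0 || beta_U < 0 || beta_V < 0)
    stop("hmf_params: regularization weights must be >= 0")
  structure(list(d = as.integer(d), c = c, alpha_U = alpha_U,
                 alpha_V = alpha_V, beta_U = beta_U, beta_V = beta_V),
            class = "hmf_params")
}

#' Confidence weights for a binary interaction matrix
#'
#' Observed interactions (r = 1) get weight \code{c > 1}; the zeros —
#' non-interactions or merely unobserved pairs — keep weight 1, encoding
#' lower confidence in the absence of an edge.
#'
#' @param R binary interaction matrix.
#' @param c confidence constant, >= 1 (\code{c = 1} gives the unweighted
#'   likelihood).
#' @return matrix of weights, same shape as \code{R}.
#' @export
confidence_weights <- function(R, c = 5) {
  if (c < 1) stop("confidence_weights: c must be >= 1")
  check_binary_matrix(R)
  1 + (c - 1) * R
}

check_binary_matrix <- function(R) {
  if (!all(R %in% c(0, 1)))
    stop("interaction matrix must be strictly binary (0/1)")
  invisible(TRUE)
}

#' Interaction probability for one drug-target pair
#'
#' The logistic link of the hyperbolic factorization model:
#' \code{p = sigmoid(-dL2)} where \code{dL2} is the squared Lorentzian
#' distance between the two latent points.  Coincident points give
#' p = 0.5; p decreases strictly as the points move apart.
#'
#' @param u,v points on the hyperboloid.
#' @return probability in (0, 1).
#' @export
interaction_probability <- function(u, v) {
  stats::plogis(-sq_lorentz_distance(u, v))
}

#' Predicted interaction probabilities for all pairs
#'
#' Vectorized over the whole embedding:
#' \code{dL2 = -2 - 2 * <U_i, V_j>_L} via one matrix product, then the
#' elementwise logistic link.
#'
#' @param U m x (d+1) matrix of drug embeddings (rows on the hyperboloid).
#' @param V n x (d+1) matrix of target embeddings.
#' @return m x n matrix of probabilities in (0, 1).
#' @export
predict_scores <- function(U, V) {
  D2 <- -2 - 2 * lorentz_gram(U, V)
  stats::plogis(-D2)
}

## numerically stable log(1 + exp(-x)); handles x of either sign so the
## finite-difference oracle can probe the loss slightly off-manifold
softplus_neg <- function(x) {
  ifelse(x > 0, log1p(exp(-x)), -x + log1p(exp(x)))
}

## prior penalty per row from the last coordinate:
##   alpha * acosh(x)^2 + (d - 1) * log(sinh(t)/t),  t = acosh(x)
## (the second term is the wrapped-normal volume correction; its limit
## at x -> 1 is 0)
prior_penalty <- function(xlast, alpha, d) {
  if (alpha == 0) return(numeric(length(xlast)))   # prior disabled entirely
  t <- acosh(pmax(xlast, 1))
  alpha * t^2 + (d - 1) * log_sinh_ratio(t)
}

## d/dx of prior_penalty, written in t = acosh(x) so both factors are
## series-stable near t = 0:
##   2 alpha t / sinh(t) + (d-1) (t cosh t - sinh t) / (t sinh^2 t)
prior_penalty_grad <- function(xlast, alpha, d) {
  if (alpha == 0) return(numeric(length(xlast)))
  t <- acosh(pmax(xlast, 1))
  small <- t < 1e-4
  g1 <- ifelse(small, 2 * alpha * (1 - t^2 / 6),
               2 * alpha * t / sinh(t))
  g2 <- ifelse(small, (d - 1) * (1 / 3 - 7 * t^2 / 90),
               (d - 1) * (t * cosh(t) - sinh(t)) / (t * sinh(t)^2))
  g1 + g2
}

## squared Lorentzian distance matrix between row sets (no clamping:
## the loss must stay differentiable off-manifold for gradient checks)
sq_dist_matrix <- function(U, V) -2 - 2 * lorentz_gram(U, V)

#' Loss of the hyperbolic logistic matrix factorization model
#'
#' Negative log posterior, up to an additive constant:
#' the confidence-weighted Bernoulli likelihood term
#' \code{sum(W * (log(1 + exp(-dL2)) + R * dL2))}, the wrapped-normal
#' prior penalties on drug and target rows, and (when similarities are
#' supplied) the hyperbolic neighborhood-regularization penalties
#' \code{beta_U * sum(S * dL2(U, U)) + beta_V * sum(T * dL2(V, V))}.
#' Additive normalization constants are dropped, so loss values are
#' comparable only within a run.
#'
#' @param U,V embeddings, rows on the hyperboloid.
#' @param R binary interaction matrix (m x n).
#' @param params an \code{\link{hmf_params}} object.
#' @param S,T optional drug-drug (m x m) and target-target (n x n)
#'   similarity matrices; diagonal terms contribute zero on-manifold.
#' @param W optional precomputed confidence weights (defaults to
#'   \code{confidence_weights(R, params$c)}).
#' @return a single finite numeric value.
#' @export
hmf_loss <- function(U, V, R, params, S = NULL, T = NULL, W = NULL) {
  if (is.null(W)) W <- confidence_weights(R, params$c)
  d <- ncol(U) - 1L
  D2 <- sq_dist_matrix(U, V)
  val <- sum(W * (softplus_neg(D2) + R * D2)) +
    sum(prior_penalty(U[, d + 1L], params$alpha_U, d)) +
    sum(prior_penalty(V[, d + 1L], params$alpha_V, d))
  if (!is.null(S) && params$beta_U > 0)
    val <- val + params$beta_U * sum(S * sq_dist_matrix(U, U))
  if (!is.null(T) && params$beta_V > 0)
    val <- val + params$beta_V * sum(T * sq_dist_matrix(V, V))
  if (!is.finite(val))
    stop("hmf_loss: non-finite loss (embedding may have diverged)")
  val
}

## Ambient partial derivatives dL/dx (no Lorentzian sign flip) of the
## loss with respect to the rows of U.  `Sim` is the drug-drug
## similarity; the symmetrized coefficient S + t(S) accounts for u^i
## appearing in both positions of the double sum.
ambient_partials_U <- function(U, V, R, W, params, Sim = NULL) {
  d <- ncol(U) - 1L
  P <- stats::plogis(-sq_dist_matrix(U, V))
  E <- W * (P - R)
  Vneg <- V; Vneg[, d + 1L] <- -Vneg[, d + 1L]
  G <- 2 * (E %*% Vneg)
  G[, d + 1L] <- G[, d + 1L] +
    prior_penalty_grad(U[, d + 1L], params$alpha_U, d)
  if (!is.null(Sim) && params$beta_U > 0) {
    Stil <- Sim + t(Sim)
    Uneg <- U; Uneg[, d + 1L] <- -Uneg[, d + 1L]
    G <- G - 2 * params$beta_U * (Stil %*% Uneg)
  }
  G
}

#' Ambient Lorentzian gradients of the loss
#'
#' Row i of each matrix is the Lorentzian ambient gradient of the loss
#' at the corresponding latent point: the vector of partial derivatives
#' with the sign of the last (time-like) component flipped, which is the
#' representation of the gradient under the Lorentzian bilinear form.
#' Projecting it onto the tangent space gives the Riemannian gradient.
#'
#' @inheritParams hmf_loss
#' @return list with components \code{U} (m x (d+1)) and \code{V}
#'   (n x (d+1)).
#' @export
hmf_gradients <- function(U, V, R, params, S = NULL, T = NULL, W = NULL) {
  if (is.null(W)) W <- confidence_weights(R, params$c)
  k <- ncol(U)
  pV <- hmf_params(d = params$d, c = params$c,
                   alpha_U = params$alpha_V, alpha_V = params$alpha_U,
                   beta_U = params$beta_V, beta_V = params$beta_U)
  GU <- ambient_partials_U(U, V, R, W, params, Sim = S)
  GV <- ambient_partials_U(V, U, t(R), t(W), pV, Sim = T)
  GU[, k] <- -GU[, k]
  GV[, k] <- -GV[, k]
  list(U = GU, V = GV)
}

#' Sparsify a similarity matrix to K nearest neighbors
#'
#' Keeps, in each row, only the K largest off-diagonal similarities
#' (zeroing the rest and the diagonal).  The result is generally
#' asymmetric; the neighborhood-regularization gradient symmetrizes
#' coefficients internally, so this is the standard NRLMF-style
#' neighborhood restriction.
#'
#' @param S square similarity matrix.
#' @param K neighbors kept per row (\code{Inf} returns S with a zeroed
#'   diagonal).
#' @return sparsified matrix of the same shape.
#' @export
knn_sparsify <- function(S, K = 5L) {
  diag(S) <- 0
  if (!is.finite(K) || K >= ncol(S) - 1L) return(S)
  out <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  for (i in seq_len(nrow(S))) {
    keep <- order(S[i, ], decreasing = TRUE)[seq_len(K)]
    out[i, keep] <- S[i, keep]
  }
  out
}
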
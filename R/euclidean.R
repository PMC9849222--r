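#' Loss of the Euclidean logistic matrix factorization baseline
#'
#' Classical neighborhood-regularized logistic MF: interaction logits are
#' dot products of d-dimensional latent rows, priors are zero-mean
#' Gaussians (ridge penalties \code{alpha * ||u||^2}), and neighborhood
#' regularization penalizes \code{beta * sum(S * ||u_i - u_j||^2)}.
#' Used as the flat-geometry comparison backend for the hyperbolic model.
#'
#' @param U m x d, V n x d latent matrices (no time-like coordinate).
#' @inheritParams hmf_loss
#' @export
lmf_loss <- function(U, V, R, params, S = NULL, T = NULL, W = NULL) {
  if (is.null(W)) W <- confidence_weights(R, params$c)
  Z <- U %*% t(V)
  # -log Bernoulli(p = sigmoid(z)): log(1 + e^z) - r z
  val <- sum(W * (softplus_neg(-Z) - R * Z)) +
    params$alpha_U * sum(U^2) + params$alpha_V * sum(V^2)
  if (!is.null(S) && params$beta_U > 0)
    val <- val + params$beta_U * euclid_pair_penalty(U, S)
  if (!is.null(T) && params$beta_V > 0)
    val <- val + params$beta_V * euclid_pair_penalty(V, T)
  if (!is.finite(val)) stop("lmf_loss: non-finite loss")
  val
}

euclid_pair_penalty <- function(U, S) {
  sq <- rowSums(U^2)
  D2 <- outer(sq, sq, "+") - 2 * (U %*% t(U))
  sum(S * D2)
}

lmf_gradient_U <- function(U, V, R, W, alpha, beta, Sim = NULL) {
  P <- stats::plogis(U %*% t(V))
  G <- (W * (P - R)) %*% V + 2 * alpha * U
  if (!is.null(Sim) && beta > 0) {
    Stil <- Sim + t(Sim)
    G <- G + 2 * beta * (rowSums(Stil) * U - Stil %*% U)
  }
  G
}

#' Euclidean gradients of the baseline loss
#'
#' @inheritParams lmf_loss
#' @return list with gradient matrices \code{U} and \code{V}.
#' @export
lmf_gradients <- function(U, V, R, params, S = NULL, T = NULL, W = NULL) {
  if (is.null(W)) W <- confidence_weights(R, params$c)
  list(U = lmf_gradient_U(U, V, R, W, params$alpha_U, params$beta_U, S),
       V = lmf_gradient_U(V, U, t(R), t(W), params$alpha_V, params$beta_V, T))
}

#' Fit the Euclidean logistic matrix factorization baseline
#'
#' Same alternating full-batch schedule, annealing and clipping as the
#' hyperbolic fit, but plain gradient descent in flat space with
#' Gaussian-prior ridge penalties.  Initialization is Gaussian with
#' variance \code{init_sigma2}.
#'
#' @inheritParams hmf_fit
#' @return an \code{"hmf_fit"} object with \code{method = "euclidean"};
#'   \code{U}, \code{V} are m x d and n x d.
#' @export
lmf_fit <- function(R, params = hmf_params(), S = NULL, T = NULL,
                    control = hmf_control()) {
  check_binary_matrix(R)
  m <- nrow(R); n <- ncol(R); d <- params$d
  W <- confidence_weights(R, params$c)
  if (!is.null(control$seed)) set.seed(as.integer(control$seed))
  sd0 <- sqrt(control$init_sigma2)
  U <- matrix(stats::rnorm(m * d, sd = sd0), m, d)
  V <- matrix(stats::rnorm(n * d, sd = sd0), n, d)
  eta <- control$eta
  trace <- numeric(0)
  for (phase in seq_len(control$phases)) {
    phase_start <- lmf_loss(U, V, R, params, S, T, W)
    for (ep in seq_len(control$epochs_per_phase)) {
      gU <- lmf_gradient_U(U, V, R, W, params$alpha_U, params$beta_U, S)
      U <- U - eta * clip_rows(gU, control$clip_norm)
      gV <- lmf_gradient_U(V, U, t(R), t(W), params$alpha_V, params$beta_V, T)
      V <- V - eta * clip_rows(gV, control$clip_norm)
      cur <- lmf_loss(U, V, R, params, S, T, W)
      if (!is.finite(cur))
        stop(sprintf("lmf_fit: loss diverged at phase %d epoch %d", phase, ep))
      trace <- c(trace, cur)
    }
    eta <- eta * control$lr_decay
  }
  converged <- length(trace) > 0 &&
    abs(phase_start - trace[length(trace)]) <=
      1e-6 * max(1, abs(phase_start))
  structure(list(U = U, V = V,
                 drug_ids = rownames(R), target_ids = colnames(R),
                 loss_trace = trace, converged = converged,
                 params = params, control = control,
                 method = "euclidean"),
            class = "hmf_fit")
}

clip_rows <- function(G, clip_norm) {
  if (!is.finite(clip_norm)) return(G)
  nrm <- sqrt(rowSums(G^2))
  sc <- ifelse(nrm > clip_norm, clip_norm / nrm, 1)
  G * sc
}
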
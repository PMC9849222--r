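#' Optimizer settings for alternating Riemannian gradient descent
#'
#' The optimizer runs a fixed number of phases; within each phase it does
#' full-batch alternating epochs (all drug rows updated with targets
#' fixed, then all target rows with drugs fixed), and between phases the
#' step size is multiplied by \code{lr_decay}.  Tangent gradients whose
#' Lorentzian norm exceeds \code{clip_norm} are rescaled to it — the
#' standard guard against the gradient blow-ups that hyperbolic descent
#' suffers far from the origin.
#'
#' @param eta initial step size, > 0.
#' @param epochs_per_phase full-batch epochs per phase.
#' @param phases number of annealing phases (default 3).
#' @param lr_decay multiplicative step-size factor between phases, in
#'   (0, 1).
#' @param clip_norm maximum Lorentzian norm of a tangent gradient
#'   (\code{Inf} disables clipping).
#' @param init_sigma2 variance of the wrapped-normal initialization at
#'   the vertex; small values start near the origin, away from the
#'   unstable rim of the embedding.
#' @param seed integer seed making the fit deterministic.
#' @param verbose print the loss every \code{verbose} epochs (0 = quiet).
#' @return an object of class \code{"hmf_control"}.
#' @export
hmf_control <- function(eta = 0.05, epochs_per_phase = 60L, phases = 3L,
                        lr_decay = 0.1, clip_norm = 1, init_sigma2 = 0.01,
                        seed = NULL, verbose = 0L) {
  if (eta <= 0) stop("hmf_control: eta must be > 0")
  if (lr_decay <= 0 || lr_decay >= 1) stop("hmf_control: lr_decay must be in (0,1)")
  if (clip_norm <= 0) stop("hmf_control: clip_norm must be > 0")
  structure(list(eta = eta, epochs_per_phase = as.integer(epochs_per_phase),
                 phases = as.integer(phases), lr_decay = lr_decay,
                 clip_norm = clip_norm, init_sigma2 = init_sigma2,
                 seed = seed, verbose = as.integer(verbose)),
            class = "hmf_control")
}

#' One Riemannian gradient descent step on the hyperboloid
#'
#' Takes the ambient Lorentzian gradient at \code{u}, projects it onto
#' the tangent space, optionally clips its Lorentzian norm, and moves
#' along the geodesic: \code{exp_map(u, -eta * grad_tangent)}.  The
#' result is re-projected onto the hyperboloid to absorb floating-point
#' drift.
#'
#' @param u point on the hyperboloid.
#' @param ambient_grad Lorentzian ambient gradient at \code{u} (last
#'   component already sign-flipped, as returned by
#'   \code{\link{hmf_gradients}}).
#' @param eta step size >= 0.
#' @param clip_norm maximum tangent-gradient norm (\code{Inf} = none).
#' @return the updated point.
#' @export
riemannian_step <- function(u, ambient_grad, eta, clip_norm = Inf) {
  if (!all(is.finite(ambient_grad)))
    stop("riemannian_step: non-finite gradient")
  g <- project_to_tangent(u, ambient_grad)
  nrm <- lorentz_norm(g)
  if (is.finite(clip_norm) && nrm > clip_norm) g <- g * (clip_norm / nrm)
  exp_map(u, -eta * g, check = FALSE)
}

## Row-wise Riemannian step for a whole embedding matrix.
## G holds Lorentzian ambient gradients (last component flipped).
riemannian_step_rows <- function(U, G, eta, clip_norm = Inf) {
  if (!all(is.finite(G))) {
    bad <- which(!apply(G, 1L, function(r) all(is.finite(r))))[1L]
    stop(sprintf("non-finite gradient in row %d", bad))
  }
  k <- ncol(U)
  Gneg <- G; Gneg[, k] <- -Gneg[, k]
  ip <- rowSums(U * Gneg)                 # <u_i, g_i>_L
  Tg <- G + ip * U                        # tangent projection, row-wise
  Tneg <- Tg; Tneg[, k] <- -Tneg[, k]
  nrm <- sqrt(pmax(rowSums(Tg * Tneg), 0))
  if (is.finite(clip_norm)) {
    sc <- ifelse(nrm > clip_norm, clip_norm / nrm, 1)
    Tg <- Tg * sc
    nrm <- pmin(nrm, clip_norm)
  }
  Y <- -eta * Tg
  t <- eta * nrm                          # Lorentzian norm of the step
  sinhc <- ifelse(t < 1e-6, 1 + t^2 / 6, sinh(t) / t)
  reproject_hyperboloid(cosh(t) * U + sinhc * Y)
}

#' Fit the hyperbolic logistic matrix factorization model
#'
#' Initializes drug and target embeddings from the wrapped normal at the
#' hyperboloid vertex, then minimizes the loss by alternating full-batch
#' Riemannian gradient descent (all drug rows, then all target rows, per
#' epoch) with phase-wise learning-rate annealing and tangent-gradient
#' clipping.
#'
#' @param R binary interaction matrix (m drugs x n targets), optionally
#'   with dimnames.
#' @param params model hyperparameters, see \code{\link{hmf_params}}.
#' @param S,T optional similarity matrices enabling neighborhood
#'   regularization (used only when the corresponding beta is > 0).
#' @param control optimizer settings, see \code{\link{hmf_control}}.
#' @return an object of class \code{"hmf_fit"}: list with \code{U},
#'   \code{V} (embeddings, rows on the hyperboloid), \code{loss_trace}
#'   (per-epoch loss after each alternating sweep), \code{converged}
#'   (relative loss change < 1e-6 across the final phase), plus the
#'   params/control used.
#' @examples
#' set.seed(1)
#' R <- matrix(rbinom(30, 1, 0.3), 6, 5)
#' fit <- hmf_fit(R, hmf_params(d = 2), control = hmf_control(seed = 1))
#' @export
hmf_fit <- function(R, params = hmf_params(), S = NULL, T = NULL,
                    control = hmf_control()) {
  check_binary_matrix(R)
  m <- nrow(R); n <- ncol(R); d <- params$d
  W <- confidence_weights(R, params$c)
  if (!is.null(control$seed)) set.seed(as.integer(control$seed))
  mu0 <- hyperboloid_vertex(d)
  U <- rwrapped_normal(m, mu0, control$init_sigma2)
  V <- rwrapped_normal(n, mu0, control$init_sigma2)
  eta <- control$eta
  trace <- numeric(0)
  for (phase in seq_len(control$phases)) {
    phase_start <- hmf_loss(U, V, R, params, S, T, W)
    for (ep in seq_len(control$epochs_per_phase)) {
      gU <- hmf_gradients(U, V, R, params, S, T, W)$U
      U <- riemannian_step_rows(U, gU, eta, control$clip_norm)
      gV <- hmf_gradients(U, V, R, params, S, T, W)$V
      V <- riemannian_step_rows(V, gV, eta, control$clip_norm)
      cur <- hmf_loss(U, V, R, params, S, T, W)
      if (!is.finite(cur))
        stop(sprintf("hmf_fit: loss diverged at phase %d epoch %d", phase, ep))
      trace <- c(trace, cur)
      if (control$verbose > 0 && ep %% control$verbose == 0)
        message(sprintf("phase %d epoch %d loss %.6f", phase, ep, cur))
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
                 method = "hyperbolic"),
            class = "hmf_fit")
}

#' @export
print.hmf_fit <- function(x, ...) {
  cat(sprintf("%s logistic matrix factorization fit\n",
              if (x$method == "hyperbolic") "Hyperbolic (Lorentz)" else "Euclidean"))
  cat(sprintf("  drugs: %d  targets: %d  latent dim: %d\n",
              nrow(x$U), nrow(x$V), x$params$d))
  if (length(x$loss_trace))
    cat(sprintf("  final loss: %.4f after %d epochs (converged: %s)\n",
                x$loss_trace[length(x$loss_trace)], length(x$loss_trace),
                x$converged))
  invisible(x)
}

#' Predicted probabilities from a fitted model
#'
#' @param object an \code{"hmf_fit"} object.
#' @param ... unused.
#' @return m x n matrix of interaction probabilities with the training
#'   dimnames.
#' @export
predict.hmf_fit <- function(object, ...) {
  P <- if (object$method == "hyperbolic") predict_scores(object$U, object$V)
       else stats::plogis(object$U %*% t(object$V))
  dimnames(P) <- list(object$drug_ids, object$target_ids)
  P
}
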
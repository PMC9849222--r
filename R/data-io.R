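#' Read a labeled binary interaction matrix
#'
#' Tab-delimited layout used by the Yamanishi gold-standard drug-target
#' sets: first row holds target identifiers, first column holds drug
#' identifiers, cells are strictly 0/1.  Some distributions ship the
#' transposed (targets x drugs) orientation; pass \code{transpose = TRUE}
#' for those.
#'
#' @param path file path.
#' @param transpose transpose after reading.
#' @return binary matrix with drug row names and target column names.
#' @export
read_interaction_matrix <- function(path, transpose = FALSE) {
  M <- read_labeled_matrix(path)
  bad <- which(!(M %in% c(0, 1)))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(M))
    stop(sprintf("non-binary cell at row '%s', column '%s': %s",
                 rownames(M)[idx[1L]], colnames(M)[idx[2L]],
                 format(M[bad[1L]])))
  }
  if (transpose) M <- t(M)
  M
}

read_labeled_matrix <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                      check.names = FALSE, comment.char = ""),
    error = function(e) stop(sprintf("malformed matrix file '%s': %s",
                                     path, conditionMessage(e))))
  M <- as.matrix(df)
  if (!is.numeric(M)) stop(sprintf("non-numeric cells in '%s'", path))
  storage.mode(M) <- "double"
  if (anyDuplicated(rownames(M)) || anyDuplicated(colnames(M)))
    stop(sprintf("duplicate row or column labels in '%s'", path))
  M
}

#' Write a labeled matrix in the tab-delimited interaction layout
#'
#' @param M matrix with row and column names.
#' @param path destination file.
#' @export
write_interaction_matrix <- function(M, path) {
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop("write_interaction_matrix: matrix must have row and column names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(M)), collapse = "\t"), con)
  body <- apply(M, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(M), body, sep = "\t"), con)
  invisible(path)
}

#' Read a labeled similarity matrix
#'
#' Same layout as \code{\link{read_interaction_matrix}} but square and
#' symmetric.  Asymmetries within \code{tol} are averaged away; larger
#' ones are an error.  Entries escaping [0, 1] by at most \code{tol} are
#' clipped with a warning.
#'
#' @param path file path.
#' @param tol symmetry / range tolerance.
#' @return symmetric numeric matrix with matching row/column labels.
#' @export
read_similarity_matrix <- function(path, tol = 1e-6) {
  M <- read_labeled_matrix(path)
  if (nrow(M) != ncol(M))
    stop(sprintf("similarity matrix in '%s' is not square", path))
  if (max(abs(M - t(M))) > tol)
    stop(sprintf("similarity matrix in '%s' is asymmetric beyond tolerance %g",
                 path, tol))
  M <- (M + t(M)) / 2
  lo <- min(M); hi <- max(M)
  if (lo < -tol || hi > 1 + tol)
    stop(sprintf("similarity entries in '%s' outside [0,1] (range %g..%g)",
                 path, lo, hi))
  if (lo < 0 || hi > 1) {
    warning(sprintf("clipping similarity entries of '%s' to [0,1]", path))
    M <- pmin(pmax(M, 0), 1)
  }
  M
}

#' Generate a model-faithful synthetic drug-target data set
#'
#' Plants drug and target embeddings drawn from the wrapped normal at
#' the hyperboloid vertex, samples Bernoulli interactions from the
#' logistic link on the squared Lorentzian distance, and derives
#' similarity matrices with a Gaussian kernel on the squared hyperbolic
#' distance (bandwidth = median squared distance).  The generator is the
#' model's own sampling distribution, so it provides ground truth for
#' parameter-recovery experiments.
#'
#' @param m,n numbers of drugs and targets.
#' @param d_true planted latent dimension.
#' @param sigma2 wrapped-normal variance of the planted embeddings.
#' @param seed integer seed (deterministic output).
#' @return list of class \code{"synthetic_dti"}: \code{R} (binary,
#'   labeled), \code{P} (planted probabilities), \code{U_true},
#'   \code{V_true}, \code{S}, \code{T} (similarities), and the generator
#'   parameters.
#' @export
generate_synthetic <- function(m, n, d_true = 3L, sigma2 = 1, seed = 1L) {
  stopifnot(m >= 1, n >= 1, d_true >= 1, sigma2 > 0)
  set.seed(as.integer(seed))
  mu0 <- hyperboloid_vertex(d_true)
  U <- rwrapped_normal(m, mu0, sigma2)
  V <- rwrapped_normal(n, mu0, sigma2)
  P <- predict_scores(U, V)
  R <- matrix(stats::rbinom(m * n, 1L, as.vector(P)), m, n)
  rownames(R) <- rownames(P) <- sprintf("drug_%03d", seq_len(m))
  colnames(R) <- colnames(P) <- sprintf("target_%03d", seq_len(n))
  S <- distance_similarity(U)
  Tm <- distance_similarity(V)
  dimnames(S) <- list(rownames(R), rownames(R))
  dimnames(Tm) <- list(colnames(R), colnames(R))
  structure(list(R = R, P = P, U_true = U, V_true = V, S = S, T = Tm,
                 m = m, n = n, d_true = d_true, sigma2 = sigma2,
                 seed = seed),
            class = "synthetic_dti")
}

## Gaussian kernel on squared hyperbolic distance; bandwidth = median
## off-diagonal squared distance (1 for degenerate clouds)
distance_similarity <- function(U) {
  G <- lorentz_gram(U, U)
  DH <- acosh(pmax(-G, 1))
  D2 <- DH^2
  tau <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(tau) || tau <= 0) tau <- 1
  S <- exp(-D2 / tau)
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Generate tree-structured synthetic drug-target data
#'
#' Embeds a regular rooted tree in the hyperbolic plane with unit-length
#' geodesic edges: the root sits at the vertex and each child is placed
#' by shooting the exponential map from its parent, with the children's
#' directions fanned around the geodesic continuation away from the
#' grandparent (the classic recursive low-distortion embedding of trees
#' into the hyperbolic plane).  Drugs sit at the leaves; targets at
#' internal-node positions (cycled and jittered by a small wrapped
#' normal when \code{n_targets} differs from the internal-node count).
#' Interactions are then sampled from the logistic link.  This yields
#' hierarchy-structured data on which low-dimensional hyperbolic
#' embeddings have a representational edge over flat ones.
#'
#' @param branching children per internal node, >= 2.
#' @param depth tree depth (leaves at depth \code{depth}), >= 1.
#' @param n_targets number of targets (default: number of internal
#'   nodes, including the root).
#' @param seed integer seed.
#' @return a \code{"synthetic_dti"} list (no planted \code{P} marginals
#'   beyond those implied by the positions).
#' @export
generate_tree_synthetic <- function(branching = 2L, depth = 3L,
                                    n_targets = NULL, seed = 1L) {
  stopifnot(branching >= 2, depth >= 1)
  set.seed(as.integer(seed))
  b <- as.integer(branching); depth <- as.integer(depth)
  nodes <- embed_regular_tree(b, depth)
  U <- nodes$pos[nodes$depth == depth, , drop = FALSE]       # leaves
  Int <- nodes$pos[nodes$depth < depth, , drop = FALSE]      # internals
  if (is.null(n_targets)) n_targets <- nrow(Int)
  idx <- rep(seq_len(nrow(Int)), length.out = n_targets)
  V <- matrix(0, n_targets, 3)
  for (i in seq_len(n_targets))
    V[i, ] <- rwrapped_normal(1, Int[idx[i], ], sigma2 = 0.05)
  P <- predict_scores(U, V)
  R <- matrix(stats::rbinom(length(P), 1L, as.vector(P)), nrow(P), ncol(P))
  rownames(R) <- rownames(P) <- sprintf("drug_%03d", seq_len(nrow(U)))
  colnames(R) <- colnames(P) <- sprintf("target_%03d", seq_len(n_targets))
  S <- distance_similarity(U)
  Tm <- distance_similarity(V)
  dimnames(S) <- list(rownames(R), rownames(R))
  dimnames(Tm) <- list(colnames(R), colnames(R))
  structure(list(R = R, P = P, U_true = U, V_true = V, S = S, T = Tm,
                 m = nrow(U), n = n_targets, d_true = 2L,
                 sigma2 = 0.05, seed = seed,
                 branching = b, depth = depth),
            class = "synthetic_dti")
}

## Recursive embedding of the regular b-ary tree of the given depth into
## H^2 with unit geodesic edges.  Each child's direction fans around the
## continuation of the parent's incoming geodesic; the root's children
## spread evenly over the full circle.  Returns positions (rows) and the
## depth of each node, root first, breadth-first.
embed_regular_tree <- function(b, depth, edge_len = 1, fan = pi / 2) {
  root <- hyperboloid_vertex(2L)
  pos <- list(root)
  depths <- 0L
  # frontier entries: point, unit tangent pointing away from the parent
  frontier <- list()
  for (k in seq_len(b)) {
    th <- 2 * pi * (k - 1) / b
    dir <- c(cos(th), sin(th), 0)
    child <- exp_map(root, edge_len * dir, check = FALSE)
    pos <- c(pos, list(child))
    depths <- c(depths, 1L)
    frontier <- c(frontier, list(list(p = child, parent = root)))
  }
  lev <- 1L
  while (lev < depth) {
    nxt <- list()
    for (node in frontier) {
      p <- node$p
      # unit tangent at p continuing away from the parent
      back <- log_map(p, node$parent, check = FALSE)
      fwd <- -back / lorentz_norm(back)
      # orthogonal direction in T_p (2-dimensional): complete the basis
      e <- c(-fwd[2], fwd[1], 0)                 # any independent ambient vector
      e <- project_to_tangent(p, e)
      e <- e - lorentz_inner(e, fwd) * fwd
      e <- e / lorentz_norm(e)
      offs <- if (b == 1L) 0 else seq(-fan / 2, fan / 2, length.out = b)
      for (k in seq_len(b)) {
        dir <- cos(offs[k]) * fwd + sin(offs[k]) * e
        child <- exp_map(p, edge_len * dir, check = FALSE)
        pos <- c(pos, list(child))
        depths <- c(depths, lev + 1L)
        nxt <- c(nxt, list(list(p = child, parent = p)))
      }
    }
    frontier <- nxt
    lev <- lev + 1L
  }
  list(pos = do.call(rbind, pos), depth = depths)
}

#' Generate synthetic data from the Euclidean logistic MF model
#'
#' Flat-space analogue of \code{\link{generate_synthetic}} for testing
#' the Euclidean baseline against its own generative model: latent rows
#' are Gaussian, interaction probabilities are the logistic of the dot
#' product, similarities use a Gaussian kernel on squared Euclidean
#' distances.
#'
#' @inheritParams generate_synthetic
#' @return a \code{"synthetic_dti"} list (with d-column \code{U_true},
#'   \code{V_true}).
#' @export
generate_synthetic_euclidean <- function(m, n, d_true = 3L, sigma2 = 1,
                                         seed = 1L) {
  stopifnot(m >= 1, n >= 1, d_true >= 1, sigma2 > 0)
  set.seed(as.integer(seed))
  U <- matrix(stats::rnorm(m * d_true, sd = sqrt(sigma2)), m, d_true)
  V <- matrix(stats::rnorm(n * d_true, sd = sqrt(sigma2)), n, d_true)
  P <- stats::plogis(U %*% t(V))
  R <- matrix(stats::rbinom(m * n, 1L, as.vector(P)), m, n)
  rownames(R) <- rownames(P) <- sprintf("drug_%03d", seq_len(m))
  colnames(R) <- colnames(P) <- sprintf("target_%03d", seq_len(n))
  esim <- function(M) {
    D2 <- as.matrix(stats::dist(M))^2
    tau <- stats::median(D2[upper.tri(D2)])
    if (!is.finite(tau) || tau <= 0) tau <- 1
    S <- exp(-D2 / tau); diag(S) <- 1; (S + t(S)) / 2
  }
  S <- esim(U); Tm <- esim(V)
  dimnames(S) <- list(rownames(R), rownames(R))
  dimnames(Tm) <- list(colnames(R), colnames(R))
  structure(list(R = R, P = P, U_true = U, V_true = V, S = S, T = Tm,
                 m = m, n = n, d_true = d_true, sigma2 = sigma2,
                 seed = seed),
            class = "synthetic_dti")
}
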
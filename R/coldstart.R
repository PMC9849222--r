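#' Lorentzian center of mass
#'
#' Weighted Fréchet mean of hyperboloid points under the squared
#' Lorentzian distance.  Unlike the geodesic (Karcher) mean, this
#' minimizer has a closed form: the weighted Euclidean average of the
#' points, rescaled back onto the hyperboloid,
#' \code{centroid = m / sqrt(-<m,m>_L)} with \code{m = sum(w_k p_k)}.
#' Invariant to positive rescaling of the weights.
#'
#' @param points matrix whose rows are hyperboloid points.
#' @param weights nonnegative weights, at least one positive (default:
#'   uniform).
#' @return a point on the hyperboloid.
#' @export
lorentz_centroid <- function(points, weights = NULL) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (length(weights) != nrow(points))
    stop("lorentz_centroid: one weight per point required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("lorentz_centroid: weights must be nonnegative with positive sum")
  m <- colSums(points * weights)
  q <- -lorentz_inner(m, m)              # > 0: average of upper-sheet points
  if (q <= 0) stop("lorentz_centroid: degenerate weighted sum")
  m / sqrt(q)
}

#' Weighted-profile cold-start imputation
#'
#' Latent vector for an entity (drug or target) with an empty
#' interaction profile: the Lorentzian center of mass of the embeddings
#' of its \code{J} most similar eligible neighbors, weighted by the
#' similarities.  This is the hyperbolic version of the weighted-profile
#' heuristic used for new-compound prediction.
#'
#' @param i row index of the cold entity.
#' @param S similarity matrix among the entities (m x m).
#' @param U embedding matrix (rows on the hyperboloid).
#' @param J number of nearest neighbors to combine (default 5; fewer are
#'   used if fewer eligible neighbors exist).
#' @param eligible indices of rows allowed as neighbors (typically rows
#'   with at least one known interaction); defaults to all rows but
#'   \code{i}.
#' @return a point on the hyperboloid.
#' @export
weighted_profile <- function(i, S, U, J = 5L, eligible = NULL) {
  if (is.null(eligible)) eligible <- setdiff(seq_len(nrow(U)), i)
  eligible <- setdiff(eligible, i)
  sims <- S[i, eligible]
  keep <- sims > 0
  if (!any(keep))
    stop("weighted_profile: cold-start failure - no neighbor with positive similarity")
  eligible <- eligible[keep]; sims <- sims[keep]
  ord <- order(sims, decreasing = TRUE)
  take <- ord[seq_len(min(J, length(ord)))]
  lorentz_centroid(U[eligible[take], , drop = FALSE], sims[take])
}

## Euclidean analogue for the baseline: similarity-weighted mean of the
## neighbor rows.
weighted_profile_euclidean <- function(i, S, U, J = 5L, eligible = NULL) {
  if (is.null(eligible)) eligible <- setdiff(seq_len(nrow(U)), i)
  eligible <- setdiff(eligible, i)
  sims <- S[i, eligible]
  keep <- sims > 0
  if (!any(keep))
    stop("weighted_profile: cold-start failure - no neighbor with positive similarity")
  eligible <- eligible[keep]; sims <- sims[keep]
  ord <- order(sims, decreasing = TRUE)
  take <- ord[seq_len(min(J, length(ord)))]
  colSums(U[eligible[take], , drop = FALSE] * sims[take]) / sum(sims[take])
}
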
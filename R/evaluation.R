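#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half — computed from midranks (equivalent to
#' exhaustive pair counting).
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in [0, 1], or \code{NA} with a warning when only one
#'   class is present.
#' @export
metric_auc <- function(labels, scores) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    warning("metric_auc: need both classes; returning NA")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation: scores are grouped by threshold (tied scores
#' enter together), and the area is the sum of recall increments times
#' the precision at each threshold.  Step-wise (not linear) PR
#' interpolation avoids over-optimistic areas.
#'
#' @inheritParams metric_auc
#' @return AUPR in [0, 1], or \code{NA} when no positive exists.
#' @export
metric_aupr <- function(labels, scores) {
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) {
    warning("metric_aupr: need both classes; returning NA")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # indices where a threshold block (run of tied scores) ends
  block_end <- which(c(sc[-length(sc)] != sc[-1], TRUE))
  tp <- cumsum(lab)[block_end]
  fp <- block_end - tp
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Average precision
#'
#' Mean of the precision at each positive's rank, with ties broken by a
#' fixed seeded permutation so the value is reproducible.
#'
#' @inheritParams metric_auc
#' @param seed seed for the tie-breaking permutation.
#' @return AP in [0, 1], or \code{NA} when no positive exists.
#' @export
metric_ap <- function(labels, scores, seed = 17L) {
  npos <- sum(labels == 1)
  if (npos == 0) {
    warning("metric_ap: no positives; returning NA")
    return(NA_real_)
  }
  lab <- labels[rank_with_tiebreak(scores, seed)]
  ranks <- which(lab == 1)
  mean(seq_along(ranks) / ranks)
}

#' Precision among the k top-scored cells
#'
#' @inheritParams metric_ap
#' @param k number of top cells (default 10).
#' @return fraction of positives among the top k.
#' @export
metric_prec_at_k <- function(labels, scores, k = 10L, seed = 17L) {
  if (length(scores) < k)
    stop("metric_prec_at_k: fewer scored cells than k")
  top <- rank_with_tiebreak(scores, seed)[seq_len(k)]
  mean(labels[top] == 1)
}

## decreasing-score ordering with a fixed seeded tie-break permutation
rank_with_tiebreak <- function(scores, seed) {
  tb <- withr_seed_sample(length(scores), seed)
  order(-scores, tb)
}

## sample.int under a local, restored RNG state
withr_seed_sample <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(n)
}

#' Cross-validation plan
#'
#' @param scheme \code{"pair_kfold"} (random partition of all
#'   drug-target cells into k groups, each tested once per round — the
#'   CVP protocol) or \code{"loocv_drug"} (one fold per drug; the fold
#'   hides the drug's whole row — the new-compound scenario).
#' @param k folds for \code{pair_kfold} (5 or 10 in common use).
#' @param rounds number of independent CV rounds.
#' @param seed integer seed controlling the partitions.
#' @return object of class \code{"cv_plan"}.
#' @export
cv_plan <- function(scheme = c("pair_kfold", "loocv_drug"), k = 5L,
                    rounds = 1L, seed = 1L) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, k = as.integer(k),
                 rounds = as.integer(rounds), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Build cross-validation fold masks
#'
#' For \code{pair_kfold}, each round partitions all m*n cells into k
#' groups; each fold's test set is one group (the training matrix is R
#' with those cells zeroed).  For \code{loocv_drug}, there are exactly m
#' folds and fold i's test set is row i.
#'
#' @param plan a \code{\link{cv_plan}}.
#' @param R interaction matrix (only its shape is used).
#' @return list of rounds; each round is a list of folds; each fold is
#'   an integer vector of test-cell indices (column-major).
#' @export
make_folds <- function(plan, R) {
  m <- nrow(R); n <- ncol(R)
  if (plan$scheme == "loocv_drug") {
    folds <- lapply(seq_len(m), function(i) i + m * (seq_len(n) - 1L))
    return(list(folds))
  }
  if (plan$k > m * n) stop("make_folds: more folds than cells")
  set.seed(plan$seed)
  lapply(seq_len(plan$rounds), function(r) {
    grp <- sample(rep_len(seq_len(plan$k), m * n))
    lapply(seq_len(plan$k), function(g) which(grp == g))
  })
}

## fit one method on a training matrix, impute cold rows/columns,
## return the full predicted score matrix
fit_and_score <- function(Rtrain, method, params, control,
                          S = NULL, T = NULL, J = 5L) {
  fit <- if (method == "hyperbolic")
    hmf_fit(Rtrain, params, S = S, T = T, control = control)
  else
    lmf_fit(Rtrain, params, S = S, T = T, control = control)
  U <- fit$U; V <- fit$V
  cold_rows <- which(rowSums(Rtrain) == 0)
  cold_cols <- which(colSums(Rtrain) == 0)
  warm_rows <- setdiff(seq_len(nrow(Rtrain)), cold_rows)
  warm_cols <- setdiff(seq_len(ncol(Rtrain)), cold_cols)
  impute <- function(i, Sim, M, warm, hyper) {
    out <- tryCatch({
      if (is.null(Sim) || !length(warm)) stop("no side information")
      if (hyper) weighted_profile(i, Sim, M, J = J, eligible = warm)
      else weighted_profile_euclidean(i, Sim, M, J = J, eligible = warm)
    }, error = function(e)
      if (hyper) hyperboloid_vertex(ncol(M) - 1L) else rep(0, ncol(M)))
    out
  }
  hyper <- method == "hyperbolic"
  for (i in cold_rows) U[i, ] <- impute(i, S, U, warm_rows, hyper)
  for (j in cold_cols) V[j, ] <- impute(j, T, V, warm_cols, hyper)
  if (hyper) predict_scores(U, V) else stats::plogis(U %*% t(V))
}

#' Run a cross-validation experiment
#'
#' Executes the plan: per round, fits the model on each fold's training
#' matrix (test cells zeroed), assembles every cell's held-out score,
#' and computes AUC, AUPR, PREC@k and AP over the round's pooled test
#' cells.  Drugs or targets whose training profile becomes empty are
#' re-embedded by the weighted-profile cold-start when similarities are
#' supplied, and fall back to the origin (hyperbolic) or the zero vector
#' (Euclidean) otherwise.
#'
#' @param R binary interaction matrix.
#' @param method \code{"hyperbolic"} or \code{"euclidean"}.
#' @param params model hyperparameters.
#' @param control optimizer settings; fold fits derive their seeds from
#'   \code{plan$seed}, so two methods run under the same plan see
#'   identical splits and paired fold seeds.
#' @param plan a \code{\link{cv_plan}}.
#' @param S,T optional similarity matrices (enable neighborhood
#'   regularization and similarity-based cold-start).
#' @param prec_k k of PREC@k (default 10).
#' @return object of class \code{"eval_report"}: \code{per_round} data
#'   frame (round, auc, aupr, prec_at_k, ap), \code{summary} with mean
#'   and sd per metric, and the score matrix of the last round.
#' @export
run_cv <- function(R, method = c("hyperbolic", "euclidean"),
                   params = hmf_params(), control = hmf_control(),
                   plan = cv_plan(), S = NULL, T = NULL, prec_k = 10L) {
  method <- match.arg(method)
  rounds <- make_folds(plan, R)
  per_round <- vector("list", length(rounds))
  scores <- NULL
  for (r in seq_along(rounds)) {
    scores <- matrix(NA_real_, nrow(R), ncol(R))
    for (f in seq_along(rounds[[r]])) {
      test_cells <- rounds[[r]][[f]]
      Rtrain <- R
      Rtrain[test_cells] <- 0
      ctl <- control
      ctl$seed <- (plan$seed * 1000L + r * 100L + f) %% .Machine$integer.max
      P <- fit_and_score(Rtrain, method, params, ctl, S, T)
      scores[test_cells] <- P[test_cells]
    }
    lab <- as.vector(R); sc <- as.vector(scores)
    per_round[[r]] <- data.frame(
      round = r,
      auc = metric_auc(lab, sc),
      aupr = metric_aupr(lab, sc),
      prec_at_k = metric_prec_at_k(lab, sc, k = prec_k, seed = plan$seed),
      ap = metric_ap(lab, sc, seed = plan$seed))
  }
  per_round <- do.call(rbind, per_round)
  agg <- data.frame(
    metric = c("auc", "aupr", "prec_at_k", "ap"),
    mean = vapply(per_round[, -1L], mean, numeric(1)),
    sd = vapply(per_round[, -1L], stats::sd, numeric(1)),
    row.names = NULL)
  structure(list(method = method, d = params$d, per_round = per_round,
                 summary = agg, scores = scores, plan = plan),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s model, d = %d, %s (%d round%s)\n", x$method, x$d,
              x$plan$scheme, nrow(x$per_round),
              if (nrow(x$per_round) > 1) "s" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %.3f +/- %.3f\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), 0, s$sd[i])))
  invisible(x)
}

#' Benchmark methods over a hyperparameter grid
#'
#' For each method, selects the grid configuration maximizing mean AUPR
#' on an inner single-round CV split (nested model selection), then
#' evaluates the winning configuration under the full plan.  Both
#' methods share the plan seed, so their folds are identical (paired
#' comparison).
#'
#' @param R binary interaction matrix.
#' @param methods character vector among
#'   \code{c("hyperbolic", "euclidean")}.
#' @param plan a \code{\link{cv_plan}} for the outer evaluation.
#' @param grid data frame of hyperparameter combinations; columns among
#'   \code{d, c, alpha_U, alpha_V, beta_U, beta_V} (missing columns use
#'   \code{\link{hmf_params}} defaults).
#' @param control optimizer settings shared by all fits.
#' @param S,T optional similarity matrices.
#' @return named list of \code{eval_report}s (one per method), each
#'   carrying the selected configuration as attribute
#'   \code{"selected"}.
#' @export
run_benchmark <- function(R, methods = c("hyperbolic", "euclidean"),
                          plan = cv_plan(), grid = NULL,
                          control = hmf_control(), S = NULL, T = NULL) {
  if (is.null(grid)) grid <- data.frame(d = c(2L, 5L, 10L))
  if (nrow(grid) == 0L) stop("run_benchmark: empty hyperparameter grid")
  inner <- cv_plan(scheme = "pair_kfold", k = plan$k, rounds = 1L,
                   seed = plan$seed + 1L)
  out <- list()
  for (method in methods) {
    best <- NULL; best_aupr <- -Inf
    for (g in seq_len(nrow(grid))) {
      p <- grid_params(grid[g, , drop = FALSE])
      rep_in <- run_cv(R, method, p, control, inner, S, T)
      a <- rep_in$summary$mean[rep_in$summary$metric == "aupr"]
      if (is.finite(a) && a > best_aupr) { best_aupr <- a; best <- p }
    }
    rep_out <- run_cv(R, method, best, control, plan, S, T)
    attr(rep_out, "selected") <- best
    out[[method]] <- rep_out
  }
  out
}

grid_params <- function(row) {
  defaults <- hmf_params()
  args <- as.list(unclass(defaults))
  for (nm in intersect(names(row), names(args))) args[[nm]] <- row[[nm]]
  do.call(hmf_params, args)
}
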
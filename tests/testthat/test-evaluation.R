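test_that("AUC: hand cases, ties, degenerate labels", {
  expect_equal(metric_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.1, 0.2)), 0.5)
  expect_equal(metric_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(metric_auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_warning(a <- metric_auc(c(1, 1), c(0.5, 0.6)), "both classes")
  expect_true(is.na(a))
})

test_that("ranking metrics equal brute-force oracles on random vectors", {
  set.seed(60)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    scores <- runif(n)                     # continuous: ties a.s. absent
    expect_equal(metric_auc(labels, scores), brute_auc(labels, scores))
    expect_equal(metric_ap(labels, scores), brute_ap(labels, scores))
    expect_equal(metric_aupr(labels, scores), brute_aupr(labels, scores))
    k <- sample(seq_len(n), 1)
    expect_equal(metric_prec_at_k(labels, scores, k),
                 brute_prec_at_k(labels, scores, k))
  }
})

test_that("perfect ranking gives all three PR metrics = 1", {
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  expect_equal(metric_aupr(labels, scores), 1)
  expect_equal(metric_ap(labels, scores), 1)
  expect_equal(metric_prec_at_k(labels, scores, 3), 1)
  expect_equal(metric_ap(c(1, 0, 0), c(0.9, 0.5, 0.1)), 1)
})

test_that("tie handling in ranked metrics is deterministic", {
  labels <- c(1, 0, 1, 0, 0)
  scores <- c(0.5, 0.5, 0.5, 0.2, 0.2)
  expect_equal(metric_prec_at_k(labels, scores, 2, seed = 3),
               metric_prec_at_k(labels, scores, 2, seed = 3))
  expect_equal(metric_ap(labels, scores, seed = 3),
               metric_ap(labels, scores, seed = 3))
})

test_that("pair_kfold folds partition every cell exactly once", {
  R <- matrix(0, 4, 5)
  plan <- cv_plan("pair_kfold", k = 5, rounds = 2, seed = 3)
  rounds <- make_folds(plan, R)
  expect_length(rounds, 2)
  for (r in rounds) {
    expect_length(r, 5)
    all_cells <- sort(unlist(r))
    expect_identical(all_cells, seq_len(20))
  }
  # determinism
  rounds2 <- make_folds(plan, R)
  expect_identical(rounds, rounds2)
})

test_that("per-drug LOOCV folds hide whole rows", {
  R <- matrix(0, 7, 4)
  folds <- make_folds(cv_plan("loocv_drug"), R)[[1]]
  expect_length(folds, 7)
  for (i in 1:7) {
    M <- matrix(FALSE, 7, 4)
    M[folds[[i]]] <- TRUE
    expect_true(all(which(rowSums(M) > 0) == i))
    expect_equal(sum(M), 4)
  }
})

test_that("run_cv produces a complete report and paired folds across methods", {
  set.seed(61)
  syn <- generate_synthetic(20, 15, d_true = 2, sigma2 = 1, seed = 8)
  plan <- cv_plan("pair_kfold", k = 5, rounds = 2, seed = 11)
  ctl <- hmf_control(eta = 0.05, epochs_per_phase = 10, phases = 2, seed = 1)
  h <- run_cv(syn$R, "hyperbolic", hmf_params(d = 2), ctl, plan)
  e <- run_cv(syn$R, "euclidean", hmf_params(d = 2), ctl, plan)
  expect_equal(nrow(h$per_round), 2)
  expect_true(all(h$per_round$auc >= 0 & h$per_round$auc <= 1))
  expect_true(all(h$summary$sd >= 0 | is.na(h$summary$sd)))
  # mean/std recomputable from the per-round values
  expect_equal(h$summary$mean[h$summary$metric == "auc"],
               mean(h$per_round$auc))
  expect_equal(h$summary$sd[h$summary$metric == "aupr"],
               stats::sd(h$per_round$aupr))
  # both methods saw identical splits (shared plan seed)
  expect_identical(make_folds(plan, syn$R), make_folds(plan, syn$R))
  expect_identical(h$plan, e$plan)
})

test_that("benchmark selects a grid configuration and reports per method", {
  set.seed(62)
  syn <- generate_synthetic(15, 12, d_true = 2, sigma2 = 1, seed = 13)
  plan <- cv_plan("pair_kfold", k = 3, rounds = 2, seed = 21)
  ctl <- hmf_control(eta = 0.05, epochs_per_phase = 8, phases = 1, seed = 1)
  out <- run_benchmark(syn$R, methods = "hyperbolic", plan = plan,
                       grid = data.frame(d = c(2L, 3L)), control = ctl)
  expect_named(out, "hyperbolic")
  expect_s3_class(attr(out$hyperbolic, "selected"), "hmf_params")
  expect_equal(nrow(out$hyperbolic$per_round), 2)
  expect_error(run_benchmark(syn$R, plan = plan, grid = data.frame()[0, ]),
               "empty")
})
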
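# brute-force metric oracles: explicit sorting / pair enumeration,
# independent of the package implementations
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

brute_ap <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  hits <- 0; s <- 0
  for (r in seq_along(lab)) {
    if (lab[r] == 1) { hits <- hits + 1; s <- s + hits / r }
  }
  s / sum(labels == 1)
}

brute_aupr <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  npos <- sum(lab == 1)
  tp <- 0; prev_rec <- 0; area <- 0
  for (r in seq_along(lab)) {
    tp <- tp + (lab[r] == 1)
    rec <- tp / npos; prec <- tp / r
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

brute_prec_at_k <- function(labels, scores, k) {
  ord <- order(scores, decreasing = TRUE)
  mean(labels[ord[seq_len(k)]] == 1)
}


fd_gradient_check <- function(m, n, d, aU, aV, bU, bV, cc, seed) {
  set.seed(seed)
  inst <- random_instance(m, n, d)
  p <- hmf_params(d = d, c = cc, alpha_U = aU, alpha_V = aV,
                  beta_U = bU, beta_V = bV)
  S <- if (bU > 0) inst$S else NULL
  Tm <- if (bV > 0) inst$T else NULL
  G <- hmf_gradients(inst$U, inst$V, inst$R, p, S, Tm)
  GU <- G$U; GU[, d + 1] <- -GU[, d + 1]       # back to raw partials
  GV <- G$V; GV[, d + 1] <- -GV[, d + 1]
  f <- function(U, V) hmf_loss(U, V, inst$R, p, S, Tm)
  h <- 1e-6; err <- 0
  for (i in seq_len(m)) for (k in seq_len(d + 1)) {
    Up <- inst$U; Up[i, k] <- Up[i, k] + h
    Um <- inst$U; Um[i, k] <- Um[i, k] - h
    num <- (f(Up, inst$V) - f(Um, inst$V)) / (2 * h)
    err <- max(err, abs(num - GU[i, k]) / max(1, abs(num)))
  }
  for (j in seq_len(n)) for (k in seq_len(d + 1)) {
    Vp <- inst$V; Vp[j, k] <- Vp[j, k] + h
    Vm <- inst$V; Vm[j, k] <- Vm[j, k] - h
    num <- (f(inst$U, Vp) - f(inst$U, Vm)) / (2 * h)
    err <- max(err, abs(num - GV[j, k]) / max(1, abs(num)))
  }
  err
}
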
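# Independent brute-force reference implementations used to cross-check the
# package. Deliberately written with explicit loops / elementwise formulas,
# never calling the code paths they verify.

oracle_knn <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
    nn <- order(d)[seq_len(k)]  # stable: ties to lower index
    A[i, nn] <- 1
  }
  pmax(A, t(A))
}

oracle_norm_adj <- function(A) {
  At <- A + diag(nrow(A))
  Dm <- diag(1 / sqrt(rowSums(At)))
  Dm %*% At %*% Dm
}

oracle_norm_ppmi <- function(P) {
  d <- rowSums(P)
  Dm <- diag(ifelse(d > 0, 1 / sqrt(d), 0), nrow(P))
  Dm %*% P %*% Dm
}

oracle_freq <- function(walks, window, n) {
  F <- matrix(0, n, n)
  for (w in walks) {
    for (s in seq_along(w)) {
      for (t in seq_along(w)) {
        if (s != t && abs(s - t) <= window) {
          F[w[s], w[t]] <- F[w[s], w[t]] + 1
        }
      }
    }
  }
  F
}

oracle_ppmi <- function(F) {
  tot <- sum(F)
  P <- matrix(0, nrow(F), ncol(F))
  for (i in seq_len(nrow(F))) {
    for (j in seq_len(ncol(F))) {
      if (F[i, j] > 0) {
        pij <- F[i, j] / tot
        pi_ <- sum(F[i, ]) / tot
        p_j <- sum(F[, j]) / tot
        P[i, j] <- max(log(pij / (pi_ * p_j)), 0)
      }
    }
  }
  P
}

# explicit-loop triple product act(S X W)
oracle_conv <- function(X, S, W, act = function(h) pmax(h, 0)) {
  n <- nrow(S); d <- ncol(X); m <- ncol(W)
  SX <- matrix(0, n, d)
  for (i in seq_len(n)) for (j in seq_len(d))
    SX[i, j] <- sum(S[i, ] * X[, j])
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <- sum(SX[i, ] * W[, j])
  act(out)
}

oracle_metrics <- function(truth, pred, prob = NULL) {
  C <- max(c(truth, pred)) + 1
  conf <- matrix(0, C, C)
  for (i in seq_along(truth)) {
    conf[truth[i] + 1, pred[i] + 1] <- conf[truth[i] + 1, pred[i] + 1] + 1
  }
  acc <- sum(diag(conf)) / sum(conf)
  prec <- rec <- f1 <- numeric(C)
  for (k in seq_len(C)) {
    prec[k] <- if (sum(conf[, k]) > 0) conf[k, k] / sum(conf[, k]) else 0
    rec[k] <- if (sum(conf[k, ]) > 0) conf[k, k] / sum(conf[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  bal <- mean(rec[rowSums(conf) > 0])
  s <- sum(conf); ctr <- sum(diag(conf))
  tk <- rowSums(conf); pk <- colSums(conf)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  mcc <- if (den > 0) (ctr * s - sum(pk * tk)) / den else 0
  auc <- NA_real_
  if (!is.null(prob) && C == 2 && length(unique(truth)) == 2) {
    pos <- prob[truth == 1]; neg <- prob[truth == 0]
    cmp <- 0
    for (a in pos) for (b in neg) cmp <- cmp + (a > b) + 0.5 * (a == b)
    auc <- cmp / (length(pos) * length(neg))
  }
  list(accuracy = acc, auc = auc, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1), mcc = mcc, balanced_accuracy = bal, confusion = conf)
}

# Central finite differences of scalar fn(params) w.r.t. every parameter
# element. fn takes the full parameter list.
numeric_grad <- function(fn, params, eps = 1e-5) {
  g <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in seq_along(p)) {
      pp <- params; pp[[nm]][i] <- p[i] + eps
      pm <- params; pm[[nm]][i] <- p[i] - eps
      g[[nm]][i] <- (fn(pp) - fn(pm)) / (2 * eps)
    }
  }
  g
}

random_sym_graph <- function(n, p_edge = 0.3) {
  A <- matrix(rbinom(n * n, 1, p_edge), n, n)
  A <- pmax(A, t(A)) * 1
  diag(A) <- 0
  A
}

# tiny deterministic separable domain pair for fast training tests
tiny_pair <- function(seed = 7, n_source = 60, n_target = 50, shift = 1.5) {
  generate_domain_pair(synthetic_spec(
    n_source = n_source, n_target = n_target, d = 6, class_sep = 4,
    shift = shift, imbalance = 0.3, noise_sd = 1, seed = seed, k = 4))
}

tiny_model_cfg <- function(...) {
  model_config(hidden1 = 16, hidden2 = 8, attention_dim = 4,
               domain_hidden = 4, ...)
}

tiny_walk_cfg <- function(seed = NULL) {
  walk_config(walks_per_node = 5, walk_length = 10, window = 3, seed = seed)
}
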
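test_that("conv_layer is act(S X W) and matches a loop-based oracle", {
  X <- matrix(rnorm(12), 4, 3)
  W <- diag(3)
  expect_equal(conv_layer(X, diag(4), W, "identity"), X)

  # edgeless graph after self-loop normalization: a per-node linear map
  op <- normalize_adjacency(matrix(0, 4, 4))
  W2 <- matrix(rnorm(6), 3, 2)
  expect_equal(conv_layer(X, op, W2, "identity"), X %*% W2)

  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:20, 1); d <- sample(1:6, 1); m <- sample(1:5, 1)
    S <- matrix(rnorm(n * n), n, n)
    X <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(d * m), d, m)
    expect_equal(conv_layer(X, S, W, "relu"), oracle_conv(X, S, W))
    expect_equal(conv_layer(X, S, W, "identity"),
                 oracle_conv(X, S, W, act = identity))
  }
  expect_error(conv_layer(X, matrix(0, 3, 3), W), class = "damgcn_dimension_error")
})

test_that("dual-channel encoding is deterministic in eval mode and shares weights across domains", {
  set.seed(77)
  fx <- worked_micro_fixture()
  cfg <- model_config(hidden1 = 8, hidden2 = 4, attention_dim = 3,
                      domain_hidden = 3)
  params <- damgcn:::init_params(2, cfg)
  f1 <- damgcn:::forward_domain(params, fx$features, fx$op_adjacency,
                                fx$op_ppmi, cfg, NULL, "full", "source")
  f2 <- damgcn:::forward_domain(params, fx$features, fx$op_adjacency,
                                fx$op_ppmi, cfg, NULL, "full", "source")
  expect_identical(f1$Z, f2$Z)
  expect_equal(dim(f1$Z_A), c(6, 4))
  expect_equal(dim(f1$Z_P), c(6, 4))
  expect_equal(dim(f1$Z), dim(f1$Z_A))

  # the target domain pass reads the literally identical weight objects:
  # perturbing the shared parameters changes both domains' encodings
  ft <- damgcn:::forward_domain(params, fx$features, fx$op_adjacency,
                                fx$op_ppmi, cfg, NULL, "full", "target")
  params2 <- params
  params2$W1_A <- params$W1_A + 0.1
  f1b <- damgcn:::forward_domain(params2, fx$features, fx$op_adjacency,
                                 fx$op_ppmi, cfg, NULL, "full", "source")
  ftb <- damgcn:::forward_domain(params2, fx$features, fx$op_adjacency,
                                 fx$op_ppmi, cfg, NULL, "full", "target")
  expect_false(identical(f1$Z_A, f1b$Z_A))
  expect_false(identical(ft$Z_A, ftb$Z_A))
  expect_identical(f1b$Z_A, ftb$Z_A)  # same inputs + shared weights
})

test_that("attention fusion is a per-node convex combination of the channels", {
  set.seed(55)
  n <- 10; h <- 4; d <- 3; a <- 5
  Z_A <- matrix(rnorm(n * h), n, h)
  Z_P <- matrix(rnorm(n * h), n, h)
  X <- matrix(rnorm(n * d), n, d)
  J <- matrix(rnorm(d * h), d, h)
  sp <- list(W = matrix(rnorm(2 * h * a), 2 * h, a), b = rnorm(a),
             v = matrix(rnorm(a), a, 1))
  fused <- attention_fuse(Z_A, Z_P, X, J, sp)
  w <- fused$weights
  expect_true(all(w$att_a >= 0 & w$att_a <= 1))
  expect_equal(w$att_a + w$att_p, rep(1, n))
  expect_equal(fused$Z, w$att_a * Z_A + w$att_p * Z_P)

  # equal channels: the fusion equals both, whatever the weights
  fused_eq <- attention_fuse(Z_A, Z_A, X, J, sp)
  expect_equal(fused_eq$Z, Z_A)

  # forcing all weight on one channel returns it exactly
  expect_equal(1 * Z_A + 0 * Z_P, Z_A)
  expect_error(attention_fuse(Z_A, Z_P, X, matrix(rnorm(d * (h + 1)), d, h + 1), sp),
               class = "damgcn_dimension_error")
})

test_that("gradient reversal is the identity forward and -lambda times upstream backward", {
  set.seed(2)
  Z <- matrix(rnorm(15), 5, 3)
  expect_identical(grad_reversal(Z), Z)

  # scalar probe: loss = sum(Q(z)) has upstream gradient 1 per element;
  # the finite difference of the negated branch -lambda*sum(z) is -lambda
  for (lambda in c(0, 0.05, 0.1)) {
    g <- grad_reversal_backward(matrix(1, 5, 3), lambda)
    expect_equal(g, matrix(-lambda, 5, 3))
    fd <- ((-lambda) * (sum(Z) + 1e-6) - (-lambda) * (sum(Z) - 1e-6)) / 2e-6
    expect_equal(g[1, 1], fd, tolerance = 1e-8)
  }
  up <- matrix(rnorm(15), 5, 3)
  expect_equal(grad_reversal_backward(up, 0.05), -0.05 * up)
  expect_equal(grad_reversal_backward(up, 0), up * 0)
})

test_that("classifier heads produce valid probabilities", {
  set.seed(12)
  cfg <- model_config(hidden1 = 8, hidden2 = 4, n_classes = 3,
                      attention_dim = 3, domain_hidden = 3)
  params <- damgcn:::init_params(5, cfg)
  Z <- matrix(rnorm(40), 10, 4)
  for (head in c("source", "target")) {
    P <- classify(Z, head, params)
    expect_equal(rowSums(P), rep(1, 10))
    expect_true(all(P > 0))
  }
  m <- classify(Z, "domain", params)
  expect_length(m, 10)
  expect_true(all(m > 0 & m < 1))
  expect_error(classify(Z, "nope", params), class = "damgcn_parameter_error")

  # zero-weight binary head: uniform logits give probability 1/2
  params$W_s <- params$W_s * 0; params$b_s <- params$b_s * 0
  cfg2 <- model_config(hidden1 = 8, hidden2 = 4, n_classes = 2)
  p2 <- damgcn:::init_params(3, cfg2)
  p2$W_s <- p2$W_s * 0
  expect_equal(classify(matrix(rnorm(8), 2, 4), "source", p2),
               matrix(0.5, 2, 2))

  # hand-set 2x2 weights against a hand-computed softmax
  p2$W_s <- matrix(0, 4, 2); p2$W_s[1, ] <- c(1, -1); p2$b_s <- c(0.5, 0)
  z <- matrix(c(2, 0, 0, 0), 1, 4)
  hand <- exp(c(2 * 1 + 0.5, 2 * -1)) / sum(exp(c(2.5, -2)))
  expect_equal(drop(classify(z, "source", p2)), hand)
})

test_that("hand-derived backpropagation matches finite differences for every parameter", {
  set.seed(101)
  n_s <- 7; n_t <- 6; d <- 3
  cfg <- model_config(hidden1 = 5, hidden2 = 4, dropout = 0, n_classes = 2,
                      attention_dim = 3, domain_hidden = 3)
  A_s <- random_sym_graph(n_s, 0.5); A_t <- random_sym_graph(n_t, 0.5)
  diag(A_s) <- 0; diag(A_t) <- 0
  A_s[1, 2] <- A_s[2, 1] <- 1; A_t[1, 2] <- A_t[2, 1] <- 1
  mkops <- function(A) {
    walks <- sample_walks(A, walk_config(4, 8, 2, seed = 5))
    P <- compute_ppmi(build_frequency_matrix(walks, 2, nrow(A)))
    list(opA = normalize_adjacency(A), opP = normalize_ppmi(P))
  }
  ops_s <- mkops(A_s); ops_t <- mkops(A_t)
  bundle <- list(
    S = list(X = matrix(rnorm(n_s * d), n_s, d), opA = ops_s$opA,
             opP = ops_s$opP, y = rep(0:1, length.out = n_s), train = 1:5),
    T = list(X = matrix(rnorm(n_t * d), n_t, d), opA = ops_t$opA,
             opP = ops_t$opP, y = rep(0:1, length.out = n_t), train = 1:4))
  params <- damgcn:::init_params(d, cfg)
  head_params <- c("W_d1", "b_d1", "w_d2", "b_d2")

  check_variant <- function(variant, lambda) {
    tcfg <- train_config(variant = variant, gamma1 = 0.9, gamma2 = 0.7)
    lg <- damgcn:::loss_and_grads(params, bundle, cfg, tcfg, lambda)
    loss_of <- function(part) function(pp) {
      r <- damgcn:::loss_and_grads(pp, bundle, cfg, tcfg, lambda)
      switch(part, cls = r$L_S + tcfg$gamma2 * r$L_T,
             da = tcfg$gamma1 * r$L_DA)
    }
    num_cls <- numeric_grad(loss_of("cls"), params)
    num_da <- if (variant == "no_domain") damgcn:::zero_like(params) else
      numeric_grad(loss_of("da"), params)
    for (nm in names(params)) {
      s <- if (nm %in% head_params) 1 else -lambda
      expected <- num_cls[[nm]] + s * num_da[[nm]]
      expect_equal(lg$grads[[nm]], expected, tolerance = 1e-5,
                   label = paste(variant, nm))
    }
  }

  check_variant("full", 0.1)
  check_variant("no_domain", 0)
  check_variant("no_global", 0.05)
  check_variant("no_target", 0.1)
})

test_that("with lambda > 0 the encoder receives the adversary's gradient reversed", {
  set.seed(17)
  # one-parameter probe: compare encoder gradients at lambda 0 vs 0.1; the
  # difference must be -0.1 times the domain-loss gradient (never aligned)
  n <- 6; d <- 2
  cfg <- model_config(hidden1 = 4, hidden2 = 3, dropout = 0,
                      attention_dim = 2, domain_hidden = 2)
  A <- random_sym_graph(n, 0.6); A[1, 2] <- A[2, 1] <- 1; diag(A) <- 0
  op <- normalize_adjacency(A)
  P <- compute_ppmi(build_frequency_matrix(
    sample_walks(A, walk_config(3, 6, 2, seed = 9)), 2, n))
  opP <- normalize_ppmi(P)
  bundle <- list(
    S = list(X = matrix(rnorm(n * d), n, d), opA = op, opP = opP,
             y = rep(0:1, 3), train = 1:4),
    T = list(X = matrix(rnorm(n * d), n, d), opA = op, opP = opP,
             y = rep(0:1, 3), train = 1:4))
  params <- damgcn:::init_params(d, cfg)
  tcfg <- train_config(variant = "full")
  g0 <- damgcn:::loss_and_grads(params, bundle, cfg, tcfg, 0)$grads
  g1 <- damgcn:::loss_and_grads(params, bundle, cfg, tcfg, 0.1)$grads
  # adversary-only contribution to the encoder at lambda = 1, with sign flipped
  diff_W1 <- (g1$W1_A - g0$W1_A) / 0.1
  # recompute the domain head's own descent direction on W1_A by finite
  # differences of L_DA alone
  fd <- numeric_grad(function(pp) {
    pfull <- params
    pfull$W1_A <- pp$W1_A
    damgcn:::loss_and_grads(pfull, bundle, cfg, tcfg, 0)$L_DA
  }, params["W1_A"])$W1_A
  expect_equal(diff_W1, -fd, tolerance = 1e-4)
})
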
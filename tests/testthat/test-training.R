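test_that("cross-entropy losses match hand evaluation", {
  # perfect one-hot predictions
  P <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(source_loss(rbind(c(1, 0), c(0, 1)), c(0L, 1L)), 0)
  # uniform binary predictions: -log 0.5 per node
  expect_equal(source_loss(matrix(0.5, 4, 2), c(0L, 1L, 0L, 1L)), log(2))
  # single node with true-class probability 0.25
  expect_equal(source_loss(matrix(c(0.25, 0.75), 1, 2), 0L), -log(0.25))
  # target loss is the same formula
  P2 <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(target_loss(P2, c(0L, 1L)), source_loss(P2, c(0L, 1L)))
  # zero probability at the true class is clamped with a warning
  expect_warning(v <- source_loss(matrix(c(0, 1), 1, 2), 0L), "clamped")
  expect_equal(v, -log(1e-12))
})

test_that("domain loss is the mean BCE and symmetric under label swap", {
  expect_equal(domain_loss(rep(0.5, 6), rep(0:1, 3)), log(2))
  expect_lt(domain_loss(c(1e-13, 1 - 1e-13), c(0, 1)), 1e-10)
  set.seed(6)
  p <- runif(20); m <- rbinom(20, 1, 0.5)
  expect_equal(domain_loss(p, m), domain_loss(1 - p, 1 - m))
})

test_that("lambda schedule ramps from 0 to the 0.1 cap; printed form is negative", {
  expect_equal(lambda_schedule(0), 0)
  expect_equal(lambda_schedule(1), 0.1)  # 2/(1+e^-10) - 1 ~ 0.99991 > cap
  expect_equal(lambda_schedule(0, mode = "as_printed"), -0.5)
  expect_true(all(lambda_schedule(seq(0, 1, 0.1), "as_printed") <= 0))
  p <- seq(0, 1, 0.05)
  l <- lambda_schedule(p)
  expect_true(all(diff(l) >= 0))
  expect_true(all(l >= 0 & l <= 0.1))
  expect_warning(lc <- lambda_schedule(1.5), "clamped")
  expect_equal(lc, 0.1)
})

test_that("stratified split keeps both classes in both partitions", {
  set.seed(44)
  y <- c(rep(0L, 40), rep(1L, 10))
  sp <- damgcn:::stratified_split(y, 0.6)
  expect_length(sp$train, 30)
  expect_equal(sum(y[sp$train] == 1), 6)
  expect_equal(sum(y[sp$test] == 1), 4)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_error(damgcn:::stratified_split(c(0L, 0L, 1L), 0.6),
               class = "damgcn_parameter_error")
})

test_that("training is deterministic and the logged total equals the weighted sum", {
  pair <- tiny_pair(seed = 3)
  tc <- train_config(epochs = 25, seed = 21)
  mc <- tiny_model_cfg()
  wc <- tiny_walk_cfg()
  fit1 <- train_damgcn(pair$source, pair$target, mc, tc, wc)
  fit2 <- train_damgcn(pair$source, pair$target, mc, tc, wc)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$params, fit2$params)

  tr <- fit1$trace
  expect_equal(tr$total,
               tr$loss_source + tc$gamma1 * tr$loss_domain +
                 tc$gamma2 * tr$loss_target,
               tolerance = 1e-12)
  expect_equal(tr$lambda[1], 0)
  expect_equal(tr$lambda[nrow(tr)], 0.1)
})

test_that("one small-step update decreases the loss on a separable toy problem", {
  pair <- tiny_pair(seed = 5)
  mc <- tiny_model_cfg(dropout = 0)
  fit1 <- train_damgcn(pair$source, pair$target, mc,
                       train_config(epochs = 1, lr = 1e-3, seed = 1),
                       tiny_walk_cfg())
  fit2 <- train_damgcn(pair$source, pair$target, mc,
                       train_config(epochs = 2, lr = 1e-3, seed = 1),
                       tiny_walk_cfg())
  expect_lt(fit2$trace$total[2], fit1$trace$total[1])
})

test_that("training drives both classification losses low on identical separable domains", {
  pair <- generate_domain_pair(synthetic_spec(
    n_source = 80, n_target = 80, d = 6, class_sep = 6, shift = 0,
    imbalance = 0.3, noise_sd = 0.5, seed = 2, k = 4))
  fit <- train_damgcn(pair$source, pair$target,
                      tiny_model_cfg(dropout = 0),
                      train_config(epochs = 150, seed = 21),
                      tiny_walk_cfg())
  last <- fit$trace[nrow(fit$trace), ]
  expect_lt(last$loss_source, 0.1)
  expect_lt(last$loss_target, 0.1)
})

test_that("ablation variants change which loss terms are active", {
  pair <- tiny_pair(seed = 13)
  mc <- tiny_model_cfg()
  wc <- tiny_walk_cfg()
  fit_nt <- train_damgcn(pair$source, pair$target, mc,
                         train_config(epochs = 5, variant = "no_target"), wc)
  expect_true(all(fit_nt$trace$loss_target == 0))
  expect_true(all(fit_nt$trace$loss_domain > 0))

  fit_nd <- train_damgcn(pair$source, pair$target, mc,
                         train_config(epochs = 5, variant = "no_domain"), wc)
  expect_true(all(fit_nd$trace$loss_domain == 0))
  expect_true(all(fit_nd$trace$lambda == 0))

  fit_ng <- train_damgcn(pair$source, pair$target, mc,
                         train_config(epochs = 5, variant = "no_global"), wc)
  expect_null(fit_ng$embeddings$source$Z_P)
  expect_identical(fit_ng$embeddings$source$Z, fit_ng$embeddings$source$Z_A)
})

test_that("the no_global variant reproduces a plain two-layer GCN code path", {
  # with the P channel removed the fused embedding IS the ConvA stack
  pair <- tiny_pair(seed = 19)
  fit <- train_damgcn(pair$source, pair$target, tiny_model_cfg(dropout = 0),
                      train_config(epochs = 3, variant = "no_global"))
  g <- pair$source
  op <- normalize_adjacency(g$adjacency)
  H1 <- conv_layer(g$features, op, fit$params$W1_A, "relu")
  Z <- conv_layer(H1, op, fit$params$W2_A, "relu")
  expect_equal(fit$embeddings$source$Z, Z)
})

test_that("mismatched feature dimensionality is rejected", {
  pair <- tiny_pair(seed = 23)
  bad <- labeled_graph(cbind(pair$target$features, 1:nrow(pair$target$features)),
                       pair$target$labels, domain_tag = "target", k = 4)
  expect_error(train_damgcn(pair$source, bad),
               class = "damgcn_dimension_error")
})

test_that("tidy, glance, predict and autoplot work on a fitted model", {
  pair <- tiny_pair(seed = 29)
  fit <- train_damgcn(pair$source, pair$target, tiny_model_cfg(),
                      train_config(epochs = 10), tiny_walk_cfg())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$accuracy_target >= 0 && gl$accuracy_target <= 1)
  pr <- predict(fit, "target", "prob")
  expect_equal(nrow(pr), nrow(pair$target$features))
  expect_equal(rowSums(as.matrix(pr)), rep(1, nrow(pr)))
  cl <- predict(fit, "target", "class")
  expect_true(all(cl %in% 0:1))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_attention(fit), "ggplot")
})
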
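#' Training configuration
#'
#' Defaults are the model's canonical configuration: 300 epochs, Adam with a
#' fixed learning rate of 3e-3, KNN with k = 6, loss balance gamma1 = 1 and
#' gamma2 = 0.8, seed 21, and a stratified 60/40 train/test split per domain.
#'
#' @param epochs Number of full-batch training steps (default 300).
#' @param lr Adam learning rate (default 0.003).
#' @param k KNN neighbours used when graphs must be built (default 6).
#' @param gamma1 Weight of the domain-adversarial loss (default 1).
#' @param gamma2 Weight of the target classifier loss (default 0.8). Set to 1
#'   for the strictly unweighted three-term objective.
#' @param seed RNG seed covering splits, walks, initialization and dropout
#'   (default 21).
#' @param train_fraction Fraction of each domain's nodes (stratified by
#'   class) used for training (default 0.6).
#' @param variant `"full"`, or an ablation: `"no_target"` (drop the target
#'   classifier loss), `"no_global"` (drop the PPMI channel and attention),
#'   `"no_domain"` (drop the gradient-reversal domain adversary).
#' @param lambda_mode `"corrected"` (default) or `"as_printed"`; see
#'   [lambda_schedule()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 300, lr = 0.003, k = 6, gamma1 = 1,
                         gamma2 = 0.8, seed = 21, train_fraction = 0.6,
                         variant = c("full", "no_target", "no_global",
                                     "no_domain"),
                         lambda_mode = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(epochs >= 1, lr > 0, k >= 1, gamma1 >= 0, gamma2 >= 0,
            train_fraction > 0, train_fraction < 1)
  structure(list(epochs = as.integer(epochs), lr = lr, k = as.integer(k),
                 gamma1 = gamma1, gamma2 = gamma2, seed = as.integer(seed),
                 train_fraction = train_fraction, variant = variant,
                 lambda_mode = lambda_mode),
            class = "train_config")
}

#' Adaptation-rate schedule for the adversarial gradient
#'
#' Controls the strength `lambda` of the reversed gradient as a function of
#' training progress `p` in `[0, 1]`. The default `"corrected"` mode is the
#' standard sigmoid ramp capped at 0.1: `min(2 / (1 + exp(-10 p)) - 1, 0.1)`,
#' which is 0 at `p = 0` and saturates at the 0.1 cap. The `"as_printed"`
#' mode evaluates `min(1 / (1 + exp(-10 p)) - 1, 0.1)` instead; that
#' expression is negative for every `p` (it equals -0.5 at `p = 0`), which
#' would make the "adversary" cooperative; it is retained only for exact
#' replication of that as-printed form.
#'
#' @param p Training progress in `[0, 1]` (vectorized). Values outside the
#'   interval are clamped with a warning.
#' @param mode `"corrected"` or `"as_printed"`.
#' @return The adaptation rate(s).
#' @examples
#' lambda_schedule(0)   # 0
#' lambda_schedule(1)   # 0.1
#' lambda_schedule(0, mode = "as_printed")  # -0.5
#' @export
lambda_schedule <- function(p, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (any(p < 0 | p > 1)) {
    warn("training progress p clamped to [0, 1]")
    p <- pmin(pmax(p, 0), 1)
  }
  ramp <- switch(mode,
                 corrected = 2 / (1 + exp(-10 * p)) - 1,
                 as_printed = 1 / (1 + exp(-10 * p)) - 1)
  pmin(ramp, 0.1)
}

clamp_probs <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

cross_entropy <- function(probs, y, eps = 1e-12) {
  probs <- as.matrix(probs)
  idx <- cbind(seq_along(y), as.integer(y) + 1L)
  p_true <- probs[idx]
  n_clamped <- sum(p_true < eps)
  list(value = mean(-log(pmax(p_true, eps))), n_clamped = n_clamped)
}

#' Source-domain classifier loss
#'
#' Mean cross-entropy `-log p(true class)` over the labeled source training
#' nodes. Probabilities below `1e-12` are clamped, with a warning, so a
#' confidently wrong prediction yields a finite loss.
#'
#' @param probs N x C row-stochastic prediction matrix.
#' @param y Integer true labels in `0..C-1`.
#' @return A single non-negative number.
#' @examples
#' source_loss(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2), c(0L, 1L))  # log(2)
#' @export
source_loss <- function(probs, y) {
  stopifnot(nrow(as.matrix(probs)) == length(y))
  ce <- cross_entropy(probs, y)
  if (ce$n_clamped > 0) {
    warn(sprintf("%d true-class probabilit%s clamped at 1e-12",
                 ce$n_clamped, if (ce$n_clamped == 1) "y" else "ies"))
  }
  ce$value
}

#' Target-domain classifier loss
#'
#' Identical contract to [source_loss()], applied to the labeled target
#' training nodes. Under the `"no_target"` ablation this term is dropped
#' from the training objective.
#'
#' @inheritParams source_loss
#' @return A single non-negative number.
#' @export
target_loss <- function(probs, y) source_loss(probs, y)

#' Domain-adversarial loss
#'
#' Mean binary cross-entropy of the domain classifier over the concatenated
#' source and target node sets. During training its gradient reaches the
#' shared encoder through the gradient-reversal layer.
#'
#' @param domain_probs Predicted probability, per node, of carrying domain
#'   label 1.
#' @param domain_labels 0/1 domain membership (source = 0, target = 1).
#' @return A single non-negative number.
#' @examples
#' domain_loss(rep(0.5, 4), c(0, 0, 1, 1))  # log(2)
#' @export
domain_loss <- function(domain_probs, domain_labels) {
  stopifnot(length(domain_probs) == length(domain_labels))
  m <- as.numeric(domain_labels)
  p <- clamp_probs(domain_probs)
  -mean(m * log(p) + (1 - m) * log(1 - p))
}

# Stratified index split: per class, round(frac * n_c) training nodes.
stratified_split <- function(y, frac) {
  train <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n_tr <- round(frac * length(idx))
    if (n_tr < 1 || n_tr >= length(idx)) {
      abort(sprintf(
        "stratification error: class %d has %d node(s); cannot split %g/%g",
        cl, length(idx), frac, 1 - frac), class = "damgcn_parameter_error")
    }
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

sample_masks <- function(n, cfg, channels) {
  if (cfg$dropout == 0) return(NULL)
  keep <- 1 - cfg$dropout
  mk <- function(nc) matrix((runif(n * nc) < keep) / keep, n, nc)
  m <- list(M1_A = mk(cfg$hidden1), M2_A = mk(cfg$hidden2))
  if (channels == 2) {
    m$M1_P <- mk(cfg$hidden1)
    m$M2_P <- mk(cfg$hidden2)
  }
  m
}

# Full joint loss and hand-derived gradients for one full-batch step.
# bundle: list(S = list(X, opA, opP, y, train), T = likewise).
# Returns losses, the total actually backpropagated, and a grads list.
loss_and_grads <- function(params, bundle, mcfg, tcfg, lambda,
                           masks_S = NULL, masks_T = NULL) {
  variant <- tcfg$variant
  fS <- forward_domain(params, bundle$S$X, bundle$S$opA, bundle$S$opP, mcfg,
                       masks_S, variant, "source")
  fT <- forward_domain(params, bundle$T$X, bundle$T$opA, bundle$T$opP, mcfg,
                       masks_T, variant, "target")
  nS <- nrow(fS$Z); nT <- nrow(fT$Z); C <- mcfg$n_classes

  grads <- list2env(zero_like(params))

  # label heads: cross-entropy on the training split of each domain
  head_pass <- function(f, dom, coef) {
    y <- bundle[[dom]]$y; tr <- bundle[[dom]]$train
    Wn <- if (dom == "S") "W_s" else "W_t"
    bn <- if (dom == "S") "b_s" else "b_t"
    probs <- classify(f$Z, if (dom == "S") "source" else "target", params)
    ce <- cross_entropy(probs[tr, , drop = FALSE], y[tr])
    Y1 <- matrix(0, length(tr), C)
    Y1[cbind(seq_along(tr), y[tr] + 1L)] <- 1
    G <- matrix(0, nrow(probs), C)
    G[tr, ] <- coef * (probs[tr, , drop = FALSE] - Y1) / length(tr)
    grads[[Wn]] <- grads[[Wn]] + t(f$Z) %*% G
    grads[[bn]] <- grads[[bn]] + colSums(G)
    list(loss = ce$value, dZ = G %*% t(params[[Wn]]))
  }

  hs <- head_pass(fS, "S", 1)
  L_S <- hs$loss
  dZ_S <- hs$dZ
  dZ_T <- matrix(0, nT, mcfg$hidden2)
  L_T <- 0
  if (variant != "no_target") {
    ht <- head_pass(fT, "T", tcfg$gamma2)
    L_T <- ht$loss
    dZ_T <- dZ_T + ht$dZ
  }

  # domain adversary behind the gradient reversal
  L_DA <- 0
  if (variant != "no_domain") {
    Zall <- grad_reversal(rbind(fS$Z, fT$Z))
    m <- c(rep(0, nS), rep(1, nT))
    pre <- sweep(Zall %*% params$W_d1, 2, params$b_d1, "+")
    Hd <- pmax(pre, 0)
    phat <- drop(sigmoid(Hd %*% params$w_d2 + params$b_d2))
    L_DA <- domain_loss(phat, m)
    dlogit <- matrix(tcfg$gamma1 * (clamp_probs(phat) - m) / (nS + nT), ncol = 1)
    grads$w_d2 <- grads$w_d2 + t(Hd) %*% dlogit
    grads$b_d2 <- grads$b_d2 + sum(dlogit)
    dHd <- (dlogit %*% t(params$w_d2)) * (pre > 0)
    grads$W_d1 <- grads$W_d1 + t(Zall) %*% dHd
    grads$b_d1 <- grads$b_d1 + colSums(dHd)
    dZ_adv <- grad_reversal_backward(dHd %*% t(params$W_d1), lambda)
    dZ_S <- dZ_S + dZ_adv[seq_len(nS), , drop = FALSE]
    dZ_T <- dZ_T + dZ_adv[nS + seq_len(nT), , drop = FALSE]
  }

  # through fusion and the shared encoder
  back_domain <- function(f, dZ, dom, masks) {
    X <- bundle[[dom]]$X
    SA <- bundle[[dom]]$opA$matrix
    if (variant == "no_global") {
      backward_channel(dZ, X, SA, f$cache, "A", masks, params, mcfg, grads)
    } else {
      datt <- backward_attention(dZ, f$cache$fuse, params, mcfg,
                                 if (dom == "S") "source" else "target", grads)
      backward_channel(datt$dZ_A, X, SA, f$cache, "A", masks, params, mcfg, grads)
      backward_channel(datt$dZ_P, X, bundle[[dom]]$opP$matrix, f$cache, "P",
                       masks, params, mcfg, grads)
    }
  }
  back_domain(fS, dZ_S, "S", masks_S)
  back_domain(fT, dZ_T, "T", masks_T)

  total <- L_S + tcfg$gamma1 * L_DA + tcfg$gamma2 * L_T
  list(L_S = L_S, L_DA = L_DA, L_T = L_T, total = total,
       grads = as.list(grads), forward = list(S = fS, T = fT))
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the domain-adaptive multichannel GCN
#'
#' Jointly minimizes `L = L_S + gamma1 * L_DA + gamma2 * L_T` by full-batch
#' Adam: the source and target cross-entropy losses on each domain's
#' stratified training split, plus the domain-adversarial binary
#' cross-entropy whose gradient reaches the shared dual-channel encoder
#' through the gradient-reversal layer with a ramped adaptation rate.
#'
#' All randomness (splits, random walks, weight initialization, dropout) is
#' seeded from `train_cfg$seed`, so a rerun with identical configurations
#' reproduces the loss trace exactly.
#'
#' @param source,target [labeled_graph()] objects with equal feature
#'   dimensionality (the encoder is shared across domains).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param walk_cfg A [walk_config()] for the global channel; its seed, when
#'   `NULL`, is derived from `train_cfg$seed`.
#' @return An object of class `damgcn_fit`: trained parameters, the
#'   per-epoch loss trace (a tibble with columns `epoch`, `loss_source`,
#'   `loss_domain`, `loss_target`, `total`, `lambda`), both graphs, splits,
#'   operators, final evaluation-mode embeddings and class probabilities.
#' @examples
#' \donttest{
#' pair <- generate_domain_pair(synthetic_spec(n_source = 60, n_target = 50,
#'                                             seed = 7))
#' fit <- train_damgcn(pair$source, pair$target,
#'                     model_config(hidden1 = 16, hidden2 = 8),
#'                     train_config(epochs = 30))
#' tail(tidy(fit))
#' }
#' @export
train_damgcn <- function(source, target, model_cfg = model_config(),
                         train_cfg = train_config(),
                         walk_cfg = walk_config()) {
  stopifnot(inherits(source, "labeled_graph"), inherits(target, "labeled_graph"))
  if (ncol(source$features) != ncol(target$features)) {
    abort(sprintf(
      "shared encoder requires equal feature dimensionality; source has %d, target %d",
      ncol(source$features), ncol(target$features)),
      class = "damgcn_dimension_error")
  }
  C <- max(c(source$labels, target$labels)) + 1L
  if (C > model_cfg$n_classes) {
    abort(sprintf("labels imply %d classes but model_config has n_classes = %d",
                  C, model_cfg$n_classes), class = "damgcn_parameter_error")
  }
  variant <- train_cfg$variant
  set.seed(train_cfg$seed)
  split_S <- stratified_split(source$labels, train_cfg$train_fraction)
  split_T <- stratified_split(target$labels, train_cfg$train_fraction)

  opA_S <- normalize_adjacency(source$adjacency)
  opA_T <- normalize_adjacency(target$adjacency)
  opP_S <- opP_T <- NULL
  ppmi <- NULL
  if (variant != "no_global") {
    wseed <- walk_cfg$seed %||% (train_cfg$seed + 1L)
    wc_S <- walk_config(walk_cfg$walks_per_node, walk_cfg$walk_length,
                        walk_cfg$window, seed = wseed)
    wc_T <- walk_config(walk_cfg$walks_per_node, walk_cfg$walk_length,
                        walk_cfg$window, seed = wseed + 1L)
    gS <- ppmi_operator(source$adjacency, wc_S)
    gT <- ppmi_operator(target$adjacency, wc_T)
    opP_S <- gS$operator; opP_T <- gT$operator
    ppmi <- list(source = gS$ppmi, target = gT$ppmi)
  }

  set.seed(train_cfg$seed)  # walks consumed a separate stream; re-anchor
  params <- init_params(ncol(source$features), model_cfg)
  state <- adam_init(params)
  bundle <- list(
    S = list(X = source$features, opA = opA_S, opP = opP_S,
             y = source$labels, train = split_S$train),
    T = list(X = target$features, opA = opA_T, opP = opP_T,
             y = target$labels, train = split_T$train))

  channels <- if (variant == "no_global") 1 else 2
  epochs <- train_cfg$epochs
  trace <- vector("list", epochs)
  for (epoch in seq_len(epochs)) {
    p <- if (epochs > 1) (epoch - 1) / (epochs - 1) else 0
    lambda <- if (variant == "no_domain") 0 else
      lambda_schedule(p, train_cfg$lambda_mode)
    masks_S <- sample_masks(nrow(source$features), model_cfg, channels)
    masks_T <- sample_masks(nrow(target$features), model_cfg, channels)
    lg <- loss_and_grads(params, bundle, model_cfg, train_cfg, lambda,
                         masks_S, masks_T)
    step <- adam_step(params, lg$grads, state, train_cfg$lr)
    params <- step$params
    state <- step$state
    trace[[epoch]] <- tibble::tibble(
      epoch = epoch, loss_source = lg$L_S, loss_domain = lg$L_DA,
      loss_target = lg$L_T, total = lg$total, lambda = lambda)
  }
  trace <- dplyr::bind_rows(trace)

  # evaluation-mode forward (dropout off)
  fS <- forward_domain(params, source$features, opA_S, opP_S, model_cfg,
                       NULL, variant, "source")
  fT <- forward_domain(params, target$features, opA_T, opP_T, model_cfg,
                       NULL, variant, "target")
  target_head <- if (variant == "no_target") "source" else "target"
  probs <- list(source = classify(fS$Z, "source", params),
                target = classify(fT$Z, target_head, params))

  structure(list(
    params = params, model_config = model_cfg, train_config = train_cfg,
    walk_config = walk_cfg, variant = variant, trace = trace,
    source = source, target = target,
    splits = list(source = split_S, target = split_T),
    operators = list(adjacency = list(source = opA_S, target = opA_T),
                     ppmi = list(source = opP_S, target = opP_T)),
    ppmi = ppmi,
    embeddings = list(
      source = list(Z_A = fS$Z_A, Z_P = fS$Z_P, Z = fS$Z, att = fS$att),
      target = list(Z_A = fT$Z_A, Z_P = fT$Z_P, Z = fT$Z, att = fT$att)),
    probs = probs),
    class = "damgcn_fit")
}

#' Predicted class probabilities or labels from a fitted model
#'
#' Transductive predictions for every node of the stored source or target
#' graph, from the evaluation-mode (dropout-off) forward pass. Under the
#' `"no_target"` ablation the target domain is scored by the source
#' classifier (direct parameter migration).
#'
#' @param object A `damgcn_fit`.
#' @param domain `"target"` (default) or `"source"`.
#' @param type `"prob"` for a tibble of class probabilities, `"class"` for
#'   integer labels.
#' @param ... Unused.
#' @return A tibble (`type = "prob"`) or integer vector (`type = "class"`).
#' @export
predict.damgcn_fit <- function(object, domain = c("target", "source"),
                               type = c("prob", "class"), ...) {
  domain <- match.arg(domain)
  type <- match.arg(type)
  P <- object$probs[[domain]]
  if (type == "class") {
    max.col(P, ties.method = "first") - 1L
  } else {
    colnames(P) <- paste0("class_", seq_len(ncol(P)) - 1L)
    tibble::as_tibble(P)
  }
}
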
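#' Encoder and head architecture configuration
#'
#' @param hidden1 Width of the first graph-convolution layer (default 128).
#' @param hidden2 Width of the second layer, i.e. the embedding dimension
#'   (default 16).
#' @param dropout Dropout probability applied after each hidden activation
#'   during training (default 0.5).
#' @param n_classes Number of outcome classes (default 2).
#' @param activation Hidden activation, `"relu"` or `"identity"`.
#' @param attention_dim Hidden width of the per-node attention scorer
#'   (default 16).
#' @param domain_hidden Hidden width of the domain classifier (default 16).
#' @param share_attention Share attention parameters across source and
#'   target domains (default `TRUE`).
#' @return An object of class `model_config`.
#' @export
model_config <- function(hidden1 = 128, hidden2 = 16, dropout = 0.5,
                         n_classes = 2, activation = c("relu", "identity"),
                         attention_dim = 16, domain_hidden = 16,
                         share_attention = TRUE) {
  activation <- match.arg(activation)
  stopifnot(hidden1 >= 1, hidden2 >= 1, dropout >= 0, dropout < 1,
            n_classes >= 2, attention_dim >= 1, domain_hidden >= 1)
  structure(list(hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 activation = activation,
                 attention_dim = as.integer(attention_dim),
                 domain_hidden = as.integer(domain_hidden),
                 share_attention = isTRUE(share_attention)),
            class = "model_config")
}

act_fun <- function(x, name) {
  switch(name, relu = pmax(x, 0), identity = x,
         abort(paste0("unknown activation: ", name)))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# All trainable tensors, keyed by role. Encoder weights (per channel) and the
# attention scorer are shared across the source and target domains; each
# domain has its own label head; the domain head sits behind the gradient
# reversal. Uses the current RNG stream.
init_params <- function(d, cfg) {
  h1 <- cfg$hidden1; h2 <- cfg$hidden2; a <- cfg$attention_dim
  hd <- cfg$domain_hidden; C <- cfg$n_classes
  p <- list(
    W1_A = glorot(d, h1), W2_A = glorot(h1, h2),
    W1_P = glorot(d, h1), W2_P = glorot(h1, h2),
    J = glorot(d, h2),
    W_att = glorot(2 * h2, a), b_att = numeric(a), v_att = glorot(a, 1),
    W_s = glorot(h2, C), b_s = numeric(C),
    W_t = glorot(h2, C), b_t = numeric(C),
    W_d1 = glorot(h2, hd), b_d1 = numeric(hd),
    w_d2 = glorot(hd, 1), b_d2 = numeric(1)
  )
  if (!cfg$share_attention) {
    p$W_att_T <- glorot(2 * h2, a); p$b_att_T <- numeric(a)
    p$v_att_T <- glorot(a, 1)
  }
  p
}

#' One graph-convolution layer
#'
#' Computes `activation(op %*% x %*% w)`. The same operation implements both
#' channels: the local channel uses the normalized adjacency operator, the
#' global channel the normalized PPMI operator.
#'
#' @param x N x d_in input matrix.
#' @param op A [normalized_operator()] (or plain N x N matrix).
#' @param w d_in x d_out weight matrix.
#' @param activation `"relu"` or `"identity"`.
#' @return The N x d_out activated output.
#' @export
conv_layer <- function(x, op, w, activation = "relu") {
  M <- if (inherits(op, "normalized_operator")) op$matrix else as.matrix(op)
  x <- as.matrix(x)
  if (ncol(M) != nrow(x)) abort("operator and input sizes disagree", class = "damgcn_dimension_error")
  if (ncol(x) != nrow(w)) abort("input and weight sizes disagree", class = "damgcn_dimension_error")
  act_fun(M %*% x %*% w, activation)
}

row_softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Dual-channel encoder for one domain. masks: list(M1_A, M2_A, M1_P, M2_P)
# of inverted-dropout masks (already scaled by 1/(1-p)) or NULL in eval mode.
# Returns Z_A, Z_P, Z, attention weights, and caches for backprop.
forward_domain <- function(params, X, op_A, op_P, cfg, masks = NULL,
                           variant = "full", domain = "source") {
  SA <- op_A$matrix
  act <- cfg$activation
  msk <- function(M, H) if (is.null(masks)) H else H * M
  H1a <- SA %*% X %*% params$W1_A
  A1a <- act_fun(H1a, act)
  D1a <- msk(masks$M1_A, A1a)
  H2a <- SA %*% D1a %*% params$W2_A
  A2a <- act_fun(H2a, act)
  Z_A <- msk(masks$M2_A, A2a)

  if (variant == "no_global") {
    return(list(Z_A = Z_A, Z_P = NULL, Z = Z_A, att = NULL,
                cache = list(H1a = H1a, A1a = A1a, D1a = D1a, H2a = H2a,
                             A2a = A2a)))
  }

  SP <- op_P$matrix
  H1p <- SP %*% X %*% params$W1_P
  A1p <- act_fun(H1p, act)
  D1p <- msk(masks$M1_P, A1p)
  H2p <- SP %*% D1p %*% params$W2_P
  A2p <- act_fun(H2p, act)
  Z_P <- msk(masks$M2_P, A2p)

  att_par <- attention_params(params, cfg, domain)
  fused <- attention_fuse(Z_A, Z_P, X, params$J, att_par)
  list(Z_A = Z_A, Z_P = Z_P, Z = fused$Z, att = fused$weights,
       cache = list(H1a = H1a, A1a = A1a, D1a = D1a, H2a = H2a, A2a = A2a,
                    H1p = H1p, A1p = A1p, D1p = D1p, H2p = H2p, A2p = A2p,
                    fuse = fused$cache))
}

attention_params <- function(params, cfg, domain) {
  if (cfg$share_attention || domain == "source") {
    list(W = params$W_att, b = params$b_att, v = params$v_att)
  } else {
    list(W = params$W_att_T, b = params$b_att_T, v = params$v_att_T)
  }
}

#' Attention fusion of the local and global channel embeddings
#'
#' Per node, scores each channel embedding against a shared projection of the
#' raw features (`J %*% x_i` brings the input to the embedding dimension),
#' normalizes the two scores with a softmax, and returns the convex
#' combination `Z = att_A * Z_A + att_P * Z_P` row-wise.
#'
#' The scorer is `s = v' tanh(W [z ; Jx] + b)` with learned `(W, b, v)`
#' shared across channels.
#'
#' @param z_a,z_p N x h channel embeddings.
#' @param x N x d raw feature matrix.
#' @param j d x h shared projection matrix.
#' @param score_params List with `W` (2h x a), `b` (length a), `v` (a x 1).
#' @return List with `Z` (fused N x h), `weights` (tibble with columns
#'   `att_a`, `att_p`, summing to 1 per node), and `cache` (internal, for
#'   backpropagation).
#' @export
attention_fuse <- function(z_a, z_p, x, j, score_params) {
  z_a <- as.matrix(z_a); z_p <- as.matrix(z_p); x <- as.matrix(x)
  U <- x %*% j
  if (ncol(U) != ncol(z_a) || ncol(z_a) != ncol(z_p)) {
    abort("projected features and channel embeddings must share dimension",
          class = "damgcn_dimension_error")
  }
  score <- function(Z) {
    Cc <- cbind(Z, U)
    Tc <- tanh(sweep(Cc %*% score_params$W, 2, score_params$b, "+"))
    list(C = Cc, T = Tc, s = drop(Tc %*% score_params$v))
  }
  sa <- score(z_a); sp <- score(z_p)
  att <- row_softmax(cbind(sa$s, sp$s))
  Z <- att[, 1] * z_a + att[, 2] * z_p
  list(Z = Z,
       weights = tibble::tibble(att_a = att[, 1], att_p = att[, 2]),
       cache = list(U = U, sa = sa, sp = sp, att = att,
                    z_a = z_a, z_p = z_p, x = x))
}

#' Gradient reversal: forward pass
#'
#' The identity map. Placed between the fused embeddings and the domain
#' classifier, it leaves activations untouched going forward while
#' [grad_reversal_backward()] multiplies the incoming gradient by `-lambda`
#' going backward, so the shared encoder learns to *maximize* the domain
#' classifier's loss.
#'
#' @param z Any numeric array.
#' @return `z`, unchanged (bit-identical).
#' @export
grad_reversal <- function(z) z

#' Gradient reversal: backward pass
#'
#' @param grad Upstream gradient flowing into the layer.
#' @param lambda Non-negative adaptation rate.
#' @return `-lambda * grad`.
#' @export
grad_reversal_backward <- function(grad, lambda) {
  stopifnot(lambda >= 0)
  -lambda * grad
}

#' Classifier heads on the fused embeddings
#'
#' Label heads (`"source"`, `"target"`) return row-stochastic class
#' probabilities via a linear map and softmax; the `"domain"` head returns a
#' per-node probability in (0,1) of belonging to the target domain (one
#' hidden ReLU layer, then a sigmoid logit).
#'
#' @param z N x h embedding matrix.
#' @param head `"source"`, `"target"` or `"domain"`.
#' @param params Model parameter list (as stored in a fitted model's
#'   `$params`).
#' @return N x C probability matrix for label heads; length-N probability
#'   vector for the domain head.
#' @export
classify <- function(z, head, params) {
  z <- as.matrix(z)
  if (head %in% c("source", "target")) {
    W <- if (head == "source") params$W_s else params$W_t
    b <- if (head == "source") params$b_s else params$b_t
    if (ncol(z) != nrow(W)) abort("embedding dimension mismatch", class = "damgcn_dimension_error")
    row_softmax(sweep(z %*% W, 2, b, "+"))
  } else if (head == "domain") {
    if (ncol(z) != nrow(params$W_d1)) abort("embedding dimension mismatch", class = "damgcn_dimension_error")
    Hd <- pmax(sweep(z %*% params$W_d1, 2, params$b_d1, "+"), 0)
    drop(sigmoid(Hd %*% params$w_d2 + params$b_d2))
  } else {
    abort(paste0("unknown head: ", head), class = "damgcn_parameter_error")
  }
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# Backward pass through the attention fusion for one domain.
# dZ: gradient at the fused embedding. Returns gradients for the channel
# embeddings and accumulates into `grads` (environment) for J and scorer.
backward_attention <- function(dZ, cache, params, cfg, domain, grads) {
  att <- cache$att; z_a <- cache$z_a; z_p <- cache$z_p
  h <- ncol(z_a)
  nm <- if (cfg$share_attention || domain == "source") {
    c(W = "W_att", b = "b_att", v = "v_att")
  } else {
    c(W = "W_att_T", b = "b_att_T", v = "v_att_T")
  }
  v <- params[[nm["v"]]]
  dZ_A <- att[, 1] * dZ
  dZ_P <- att[, 2] * dZ
  da_A <- rowSums(dZ * z_a)
  da_P <- rowSums(dZ * z_p)
  dot <- att[, 1] * da_A + att[, 2] * da_P
  ds_A <- att[, 1] * (da_A - dot)
  ds_P <- att[, 2] * (da_P - dot)
  dU <- matrix(0, nrow(z_a), h)
  for (ch in c("A", "P")) {
    sc <- if (ch == "A") cache$sa else cache$sp
    ds <- if (ch == "A") ds_A else ds_P
    dT <- outer(ds, drop(v))
    grads[[nm["v"]]] <- grads[[nm["v"]]] + t(sc$T) %*% ds
    dpre <- dT * (1 - sc$T^2)
    grads[[nm["W"]]] <- grads[[nm["W"]]] + t(sc$C) %*% dpre
    grads[[nm["b"]]] <- grads[[nm["b"]]] + colSums(dpre)
    dC <- dpre %*% t(params[[nm["W"]]])
    if (ch == "A") dZ_A <- dZ_A + dC[, seq_len(h)] else dZ_P <- dZ_P + dC[, seq_len(h)]
    dU <- dU + dC[, h + seq_len(h)]
  }
  grads$J <- grads$J + t(cache$x) %*% dU
  list(dZ_A = dZ_A, dZ_P = dZ_P)
}

# Backward pass through one channel's two conv layers (shared weights
# accumulated into `grads`). dZc: gradient at the channel output.
backward_channel <- function(dZc, X, S, cache, ch, masks, params, cfg, grads) {
  suf <- if (ch == "A") "a" else "p"
  W2n <- paste0("W2_", ch); W1n <- paste0("W1_", ch)
  H2 <- cache[[paste0("H2", suf)]]; H1 <- cache[[paste0("H1", suf)]]
  D1 <- cache[[paste0("D1", suf)]]
  M1 <- masks[[paste0("M1_", ch)]]; M2 <- masks[[paste0("M2_", ch)]]
  dA2 <- if (is.null(masks)) dZc else dZc * M2
  dH2 <- if (cfg$activation == "relu") dA2 * (H2 > 0) else dA2
  SdH2 <- S %*% dH2  # S symmetric
  grads[[W2n]] <- grads[[W2n]] + t(D1) %*% SdH2
  dD1 <- SdH2 %*% t(params[[W2n]])
  dA1 <- if (is.null(masks)) dD1 else dD1 * M1
  dH1 <- if (cfg$activation == "relu") dA1 * (H1 > 0) else dA1
  grads[[W1n]] <- grads[[W1n]] + t(X) %*% (S %*% dH1)
  invisible(NULL)
}
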
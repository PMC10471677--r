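#' Random-walk configuration for the global-consistency channel
#'
#' The global channel treats sampled random walks as sentences and nodes as
#' words: node-context co-occurrence counts within a window feed a positive
#' pointwise mutual information (PPMI) matrix.
#'
#' @param walks_per_node Number of walks started from each non-isolated node
#'   (default 10).
#' @param walk_length Number of steps per walk; each walk visits
#'   `walk_length + 1` nodes (default 40).
#' @param window Co-occurrence radius within a walk (default 5); must not
#'   exceed `walk_length`.
#' @param seed Integer RNG seed for walk sampling, or `NULL` to let the
#'   training loop derive one from its own seed.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(walks_per_node = 10, walk_length = 40, window = 5,
                        seed = NULL) {
  stopifnot(walks_per_node >= 1, walk_length >= 1, window >= 1)
  if (window > walk_length) {
    abort("window must not exceed walk_length", class = "damgcn_parameter_error")
  }
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "walk_config")
}

#' Row-stochastic transition matrix of a random walk
#'
#' Row `i` is `A[i, ] / sum_j A[i, j]`: the probability of stepping from node
#' `i` to each neighbour. Isolated nodes (degree zero) keep an all-zero row,
#' are excluded from walk starts, and trigger a warning.
#'
#' @param adjacency Symmetric non-negative adjacency matrix.
#' @return A matrix whose non-isolated rows each sum to 1.
#' @examples
#' transition_matrix(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
transition_matrix <- function(adjacency) {
  A <- as.matrix(adjacency)
  deg <- rowSums(A)
  isolated <- deg == 0
  if (any(isolated)) {
    warn(sprintf("%d isolated node(s) excluded from random walks: %s",
                 sum(isolated),
                 paste(head(which(isolated), 10), collapse = ", ")))
  }
  P <- A
  P[!isolated, ] <- A[!isolated, , drop = FALSE] / deg[!isolated]
  P
}

#' Sample a random-walk corpus over a graph
#'
#' Starts `walks_per_node` walks from every non-isolated node and advances
#' each one `walk_length` steps, sampling the next node from the current
#' node's transition-matrix row. Reproducible given `cfg$seed`.
#'
#' @param adjacency Symmetric non-negative adjacency matrix.
#' @param cfg A [walk_config()]; its `seed` must be set.
#' @return A list of integer vectors of node indices (1-based), each of
#'   length `walk_length + 1`. An edgeless graph yields an empty list with a
#'   warning.
#' @export
sample_walks <- function(adjacency, cfg) {
  stopifnot(inherits(cfg, "walk_config"))
  if (is.null(cfg$seed)) {
    abort("walk_config seed must be set before sampling", class = "damgcn_parameter_error")
  }
  A <- as.matrix(adjacency)
  n <- nrow(A)
  deg <- rowSums(A)
  starts_pool <- which(deg > 0)
  if (length(starts_pool) == 0) {
    warn("graph has no edges; returning an empty walk corpus")
    return(list())
  }
  set.seed(cfg$seed)
  nbrs <- vector("list", n)
  cums <- vector("list", n)
  for (v in starts_pool) {
    nb <- which(A[v, ] > 0)
    nbrs[[v]] <- nb
    cums[[v]] <- cumsum(A[v, nb] / deg[v])
  }
  starts <- rep(starts_pool, each = cfg$walks_per_node)
  nw <- length(starts)
  walks <- matrix(0L, nrow = nw, ncol = cfg$walk_length + 1L)
  walks[, 1] <- starts
  cur <- starts
  for (t in seq_len(cfg$walk_length)) {
    u <- runif(nw)
    nxt <- integer(nw)
    by_v <- split(seq_len(nw), cur)
    for (vs in names(by_v)) {
      v <- as.integer(vs)
      idx <- by_v[[vs]]
      pos <- findInterval(u[idx], cums[[v]]) + 1L
      pos[pos > length(nbrs[[v]])] <- length(nbrs[[v]])
      nxt[idx] <- nbrs[[v]][pos]
    }
    walks[, t + 1L] <- nxt
    cur <- nxt
  }
  lapply(seq_len(nw), function(i) walks[i, ])
}

#' Node-context co-occurrence frequency matrix from walks
#'
#' `F[i, j]` counts ordered (center = node i, context = node j) pairs whose
#' positions within a walk are at most `window` apart (distinct positions),
#' aggregated over the whole corpus — the skip-gram count matrix of the walk
#' "sentences".
#'
#' @param walks List of integer node-index vectors (1-based).
#' @param window Co-occurrence radius.
#' @param n_nodes Number of nodes in the graph.
#' @return An `n_nodes` x `n_nodes` non-negative count matrix.
#' @examples
#' build_frequency_matrix(list(c(1L, 2L)), window = 1, n_nodes = 2)
#' @export
build_frequency_matrix <- function(walks, window, n_nodes) {
  if (length(walks) == 0) return(matrix(0, n_nodes, n_nodes))
  flats <- vector("list", length(walks))
  for (k in seq_along(walks)) {
    w <- as.integer(walks[[k]])
    if (any(w > n_nodes) || any(w < 1)) {
      abort("walk contains a node index outside 1..n_nodes",
            class = "damgcn_parameter_error")
    }
    L <- length(w)
    per_d <- vector("list", min(window, L - 1L))
    for (d in seq_len(min(window, L - 1L))) {
      a <- w[seq_len(L - d)]
      b <- w[seq_len(L - d) + d]
      # ordered pairs in both directions: (center a, context b) and (b, a)
      per_d[[d]] <- c((a - 1L) * n_nodes + b, (b - 1L) * n_nodes + a)
    }
    flats[[k]] <- unlist(per_d)
  }
  counts <- tabulate(unlist(flats), nbins = n_nodes * n_nodes)
  matrix(counts, n_nodes, n_nodes, byrow = TRUE)
}

#' Positive pointwise mutual information matrix
#'
#' From a frequency matrix `F`, forms joint probabilities
#' `p_ij = F_ij / sum(F)`, marginals `p_i.` and `p_.j`, and returns
#' `max(log(p_ij / (p_i. p_.j)), 0)` (natural log). Entries with `F_ij = 0`
#' are 0, and any pair whose joint equals the product of its marginals maps
#' exactly to 0 — statistically independent node-context pairs carry no
#' semantic signal.
#'
#' @param freq Non-negative count matrix with positive total.
#' @return A non-negative matrix of the same dimension.
#' @examples
#' compute_ppmi(matrix(c(2, 0, 0, 2), 2, 2))  # diag log(2), off-diag 0
#' @export
compute_ppmi <- function(freq) {
  F <- as.matrix(freq)
  if (any(F < 0)) abort("frequency matrix must be non-negative", class = "damgcn_parameter_error")
  tot <- sum(F)
  if (tot <= 0) {
    abort("frequency matrix is all zero: need a non-empty walk corpus",
          class = "damgcn_parameter_error")
  }
  joint <- F / tot
  pr <- rowSums(joint)
  pc <- colSums(joint)
  P <- matrix(0, nrow(F), ncol(F))
  nz <- F > 0
  P[nz] <- log(joint[nz] / (pr[row(F)[nz]] * pc[col(F)[nz]]))
  P[P < 0] <- 0
  P
}

#' Symmetric degree normalization of a PPMI matrix
#'
#' With `D_ii = sum_j P_ij`, returns `D^{-1/2} P D^{-1/2}`, the diffusion
#' operator of the global-consistency graph convolution. Rows of `P` with
#' zero sum (e.g. isolated nodes) stay zero.
#'
#' @param ppmi Non-negative matrix from [compute_ppmi()].
#' @return A [normalized_operator()] with `flavor = "ppmi"`.
#' @export
normalize_ppmi <- function(ppmi) {
  P <- as.matrix(ppmi)
  if (any(P < 0)) abort("PPMI matrix must be non-negative", class = "damgcn_parameter_error")
  d <- rowSums(P)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  op <- dinv * P * rep(dinv, each = nrow(P))
  normalized_operator(op, "ppmi")
}

#' Build the global-consistency operator for a graph in one call
#'
#' Pipeline: sample walks, count co-occurrences, PPMI transform, symmetric
#' degree normalization. With `cache_dir` set, the frequency and PPMI
#' matrices are stored on disk keyed by a hash of the adjacency matrix and
#' the walk configuration, so reruns over the same graph skip walk sampling.
#'
#' @param adjacency Symmetric non-negative adjacency matrix.
#' @param cfg A [walk_config()] with its `seed` set.
#' @param cache_dir Optional directory for the on-disk cache.
#' @return A list with elements `operator` (a [normalized_operator()],
#'   flavor `"ppmi"`), `ppmi` and `freq` matrices.
#' @export
ppmi_operator <- function(adjacency, cfg, cache_dir = NULL) {
  A <- as.matrix(adjacency)
  if (!is.null(cache_dir)) {
    key <- rlang::hash(list(A, cfg$walks_per_node, cfg$walk_length,
                            cfg$window, cfg$seed))
    cache_file <- file.path(cache_dir, paste0("ppmi-", key, ".rds"))
    if (file.exists(cache_file)) {
      hit <- readRDS(cache_file)
      return(list(operator = normalize_ppmi(hit$ppmi), ppmi = hit$ppmi,
                  freq = hit$freq))
    }
  }
  walks <- sample_walks(A, cfg)
  F <- build_frequency_matrix(walks, cfg$window, nrow(A))
  P <- compute_ppmi(F)
  if (!is.null(cache_dir)) {
    if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
    saveRDS(list(freq = F, ppmi = P), cache_file)
  }
  list(operator = normalize_ppmi(P), ppmi = P, freq = F)
}
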
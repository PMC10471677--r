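#' Specification of a synthetic source/target domain pair
#'
#' Describes two class-structured tabular domains that share label semantics
#' but differ in feature distribution (covariate shift) and size — the
#' statistical shape of related clinical cohorts: d features, a rare positive
#' outcome, a larger source cohort than target. Features are class-conditional
#' Gaussians with shared centroid geometry; the target domain applies a
#' rotation and a mean offset, both scaled by `shift`, so label semantics are
#' preserved while the marginals move.
#'
#' @param n_source,n_target Cohort sizes (defaults 300 and 200). Each must be
#'   at least `2 k + 2` so the KNN graph is well posed.
#' @param d Number of features (default 25).
#' @param n_classes Number of outcome classes (default 2); requires
#'   `d >= n_classes`.
#' @param class_sep Euclidean distance between class centroids, in noise
#'   standard deviations when `noise_sd = 1` (default 3).
#' @param shift Covariate-shift magnitude: the target mean offset has norm
#'   `shift` and the target rotation angle is `0.2 * shift` radians
#'   (default 1.5). `shift = 0` makes the two domains identically
#'   distributed.
#' @param imbalance Positive-class (label `C-1`) fraction (default 0.15,
#'   a rare outcome); must give at least 2 positives per domain.
#' @param noise_sd Within-class feature standard deviation (default 1).
#' @param seed RNG seed (default 1).
#' @param k KNN neighbours for graph construction (default 6).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_source = 300, n_target = 200, d = 25,
                           n_classes = 2, class_sep = 3, shift = 1.5,
                           imbalance = 0.15, noise_sd = 1, seed = 1, k = 6) {
  stopifnot(d >= 1, n_classes >= 2, d >= n_classes, class_sep >= 0,
            shift >= 0, imbalance > 0, imbalance < 1, noise_sd > 0)
  spec <- structure(list(n_source = as.integer(n_source),
                         n_target = as.integer(n_target), d = as.integer(d),
                         n_classes = as.integer(n_classes),
                         class_sep = class_sep, shift = shift,
                         imbalance = imbalance, noise_sd = noise_sd,
                         seed = as.integer(seed), k = as.integer(k)),
                    class = "synthetic_spec")
  for (n in c(spec$n_source, spec$n_target)) {
    if (n < 2 * spec$k + 2) {
      abort(sprintf("domain size %d too small for k = %d (need >= %d)",
                    n, spec$k, 2 * spec$k + 2), class = "damgcn_parameter_error")
    }
    if (round(spec$imbalance * n) < 2) {
      abort("imbalance * n must be at least 2 per domain",
            class = "damgcn_parameter_error")
    }
  }
  spec
}

draw_labels <- function(n, spec) {
  n_pos <- round(spec$imbalance * n)
  rest <- n - n_pos
  if (spec$n_classes == 2) {
    y <- c(rep(0L, rest), rep(1L, n_pos))
  } else {
    base <- rep(0:(spec$n_classes - 2L), length.out = rest)
    y <- c(sort(base), rep(spec$n_classes - 1L, n_pos))
  }
  sample(y)
}

#' Generate a paired source/target transfer problem
#'
#' Draws both domains from the generative model described in
#' [synthetic_spec()] and builds their KNN graphs, so every pipeline stage —
#' graph construction, walks, PPMI, training, evaluation — is exercisable
#' without external data. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `source` and `target`, both
#'   [labeled_graph()] objects.
#' @examples
#' pair <- generate_domain_pair(synthetic_spec(n_source = 60, n_target = 40,
#'                                             seed = 3))
#' pair$source
#' @export
generate_domain_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  d <- spec$d; C <- spec$n_classes
  # orthonormal centroid directions: all pairwise centroid distances equal
  B <- qr.Q(qr(matrix(rnorm(d * C), d, C)))
  mu <- t(B) * spec$class_sep / sqrt(2)  # C x d, row c = centroid of class c

  y_s <- draw_labels(spec$n_source, spec)
  X_s <- mu[y_s + 1L, , drop = FALSE] +
    matrix(rnorm(spec$n_source * d, sd = spec$noise_sd), spec$n_source, d)

  # target transform: rotation by 0.2*shift radians in a random 2-plane,
  # then a mean offset of norm `shift`
  Q2 <- qr.Q(qr(matrix(rnorm(d * 2), d, 2)))
  u1 <- Q2[, 1]; u2 <- Q2[, 2]
  theta <- 0.2 * spec$shift
  R <- diag(d) + (cos(theta) - 1) * (tcrossprod(u1) + tcrossprod(u2)) +
    sin(theta) * (tcrossprod(u2, u1) - tcrossprod(u1, u2))
  off_dir <- rnorm(d)
  off <- if (spec$shift > 0) spec$shift * off_dir / sqrt(sum(off_dir^2)) else numeric(d)

  y_t <- draw_labels(spec$n_target, spec)
  X_t_raw <- mu[y_t + 1L, , drop = FALSE] +
    matrix(rnorm(spec$n_target * d, sd = spec$noise_sd), spec$n_target, d)
  X_t <- X_t_raw %*% t(R) + matrix(off, spec$n_target, d, byrow = TRUE)

  list(source = labeled_graph(X_s, y_s, domain_tag = "source", k = spec$k),
       target = labeled_graph(X_t, y_t, domain_tag = "target", k = spec$k))
}

#' A deterministic six-node worked example
#'
#' A tiny two-community graph (two triangles joined by a bridge), a fixed
#' four-walk corpus over it, and the hand-checked frequency and PPMI matrices
#' that corpus induces with window 1. Every nonzero PPMI entry has a closed
#' form: `log(F_ij * 24 / (r_i * r_j))` with `r` the row sums of `F`, e.g.
#' `log 4` for the (1,2) pair. Used in unit tests and documentation.
#'
#' @return A list with `adjacency`, `features` (6 x 2), `labels`, `walks`,
#'   `window`, `freq`, `ppmi`, and the two normalized operators
#'   `op_adjacency`, `op_ppmi`.
#' @export
worked_micro_fixture <- function() {
  A <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- 1
    A[edges[r, 2], edges[r, 1]] <- 1
  }
  X <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 3, 3, 3.5, 3, 3, 3.5),
              nrow = 6, byrow = TRUE)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  walks <- list(c(1L, 2L, 3L, 4L), c(4L, 5L, 6L, 4L),
                c(3L, 1L, 2L, 3L), c(6L, 5L, 4L, 3L))
  F <- matrix(c(0, 2, 1, 0, 0, 0,
                2, 0, 2, 0, 0, 0,
                1, 2, 0, 2, 0, 0,
                0, 0, 2, 0, 2, 1,
                0, 0, 0, 2, 0, 2,
                0, 0, 0, 1, 2, 0), nrow = 6, byrow = TRUE)
  # closed-form PPMI of F above: total 24, row sums (3, 4, 5, 5, 4, 3)
  l4 <- log(4); l16 <- log(1.6); l24 <- log(2.4); l192 <- log(1.92)
  P <- matrix(c(0,   l4,  l16, 0,    0,   0,
                l4,  0,   l24, 0,    0,   0,
                l16, l24, 0,   l192, 0,   0,
                0,   0,   l192, 0,   l24, l16,
                0,   0,   0,   l24,  0,   l4,
                0,   0,   0,   l16,  l4,  0), nrow = 6, byrow = TRUE)
  list(adjacency = A, features = X, labels = y, walks = walks, window = 1L,
       freq = F, ppmi = P,
       op_adjacency = normalize_adjacency(A),
       op_ppmi = normalize_ppmi(P))
}
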
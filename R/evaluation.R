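#' Classification metric suite for imbalanced outcomes
#'
#' Computes, from true and predicted labels (plus positive-class
#' probabilities for AUC), the seven statistics used throughout the package:
#' accuracy, AUC, macro-averaged precision, recall and F1, the Matthews
#' correlation coefficient, and balanced accuracy (mean per-class recall).
#' Macro averaging weighs both classes equally regardless of prevalence,
#' which matters for rare-outcome clinical data.
#'
#' AUC uses the rank (Mann-Whitney) formulation on the positive-class
#' probabilities and is reported only for binary problems; a single-class
#' truth vector yields `NA` with a warning. MCC uses the multiclass
#' generalization (Gorodkin), which reduces to the familiar 2x2 formula for
#' binary labels. Degenerate denominators (an empty predicted class, a
#' constant confusion matrix) yield 0 for the affected statistic.
#'
#' @param truth Integer true labels in `0..C-1`.
#' @param pred Integer predicted labels.
#' @param pos_probs Optional predicted probability of the positive class
#'   (label `C-1`), used only for AUC.
#' @param task_name Optional label for the evaluated transfer task (e.g.
#'   `"H->D"`).
#' @return A one-row tibble with columns `task`, `n`, `accuracy`, `auc`,
#'   `precision`, `recall`, `f1`, `mcc`, `balanced_accuracy`; the C x C
#'   confusion matrix (true in rows) is attached as attribute
#'   `"confusion"`.
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1), c(0.2, 0.6, 0.7, 0.9))
#' @export
compute_metrics <- function(truth, pred, pos_probs = NULL,
                            task_name = NA_character_) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  if (!is.null(pos_probs)) stopifnot(length(pos_probs) == length(truth))
  C <- max(c(truth, pred)) + 1L
  lev <- 0:(C - 1L)
  conf <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  conf <- matrix(as.numeric(conf), C, C, dimnames = dimnames(conf))
  n <- sum(conf)

  accuracy <- sum(diag(conf)) / n
  prec <- rec <- f1 <- numeric(C)
  for (k in seq_len(C)) {
    tp <- conf[k, k]
    colk <- sum(conf[, k]); rowk <- sum(conf[k, ])
    prec[k] <- if (colk > 0) tp / colk else 0
    rec[k] <- if (rowk > 0) tp / rowk else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  balanced <- mean(rec[rowSums(conf) > 0])

  # Gorodkin multiclass MCC; reduces to (TP TN - FP FN)/sqrt(...) for C = 2
  s <- n; c_tr <- sum(diag(conf))
  tk <- rowSums(conf); pk <- colSums(conf)
  num <- c_tr * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  mcc <- if (den > 0) num / den else 0

  auc <- NA_real_
  if (!is.null(pos_probs)) {
    if (length(unique(truth)) < 2) {
      warn("AUC undefined: truth vector has a single class")
    } else if (C == 2) {
      auc <- auc_rank(pos_probs, truth)
    } else {
      warn("AUC reported only for binary problems")
    }
  }

  out <- tibble::tibble(task = task_name, n = n, accuracy = accuracy,
                        auc = auc, precision = mean(prec), recall = mean(rec),
                        f1 = mean(f1), mcc = mcc,
                        balanced_accuracy = balanced)
  attr(out, "confusion") <- conf
  out
}

# Mann-Whitney AUC with midranks for ties.
auc_rank <- function(prob, truth) {
  r <- rank(prob)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted model on a stored split
#'
#' @param fit A `damgcn_fit`.
#' @param domain `"target"` (default) or `"source"`.
#' @param split `"test"` (default), `"train"`, or `"all"`.
#' @param task_name Optional task label carried into the report.
#' @return A one-row metrics tibble from [compute_metrics()].
#' @export
evaluate_fit <- function(fit, domain = c("target", "source"),
                         split = c("test", "train", "all"),
                         task_name = NA_character_) {
  stopifnot(inherits(fit, "damgcn_fit"))
  domain <- match.arg(domain)
  split <- match.arg(split)
  g <- fit[[domain]]
  idx <- switch(split, all = seq_along(g$labels),
                fit$splits[[domain]][[split]])
  P <- fit$probs[[domain]]
  pred <- max.col(P, ties.method = "first") - 1L
  pos <- if (ncol(P) == 2) P[, 2] else NULL
  compute_metrics(g$labels[idx], pred[idx],
                  if (is.null(pos)) NULL else pos[idx], task_name)
}

#' Run one cross-domain transfer task
#'
#' Trains the model with the named source and target domains and reports the
#' metric suite on the target test split (the headline quantity) and on the
#' source test split (adversarial adaptation tends to help the source task
#' too).
#'
#' @param source_name,target_name Names of entries in `datasets`.
#' @param datasets Named list of [labeled_graph()] objects.
#' @param model_cfg,train_cfg,walk_cfg Configurations passed to
#'   [train_damgcn()].
#' @return A list with `fit` (the trained model) and `metrics` (a two-row
#'   tibble, one row per evaluated domain, with a `domain` column and the
#'   task tag `"<source>-><target>"`).
#' @export
run_transfer_task <- function(source_name, target_name, datasets,
                              model_cfg = model_config(),
                              train_cfg = train_config(),
                              walk_cfg = walk_config()) {
  for (nm in c(source_name, target_name)) {
    if (!nm %in% names(datasets)) {
      abort(sprintf("unknown dataset '%s'; available: %s", nm,
                    paste(names(datasets), collapse = ", ")),
            class = "damgcn_parameter_error")
    }
  }
  src <- datasets[[source_name]]; tgt <- datasets[[target_name]]
  src$domain_tag <- "source"; tgt$domain_tag <- "target"
  fit <- train_damgcn(src, tgt, model_cfg, train_cfg, walk_cfg)
  task <- paste0(source_name, "->", target_name)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(evaluate_fit(fit, "target", "test", task), domain = "target"),
    dplyr::mutate(evaluate_fit(fit, "source", "test", task), domain = "source"))
  list(fit = fit, metrics = dplyr::relocate(metrics, "domain", .after = "task"))
}

#' Ablation grid over model variants and seeds
#'
#' Trains the full model and the requested ablations (`no_target`: drop the
#' target classifier loss; `no_global`: drop the PPMI channel and attention;
#' `no_domain`: drop the gradient-reversal adversary) across seeds, and
#' reports target-test metrics per run.
#'
#' @param source,target [labeled_graph()] objects.
#' @param variants Character vector of variants to run.
#' @param seeds Integer vector of training seeds.
#' @param model_cfg,train_cfg,walk_cfg Configurations; `train_cfg$variant`
#'   and `train_cfg$seed` are overridden per run.
#' @return A tibble with one row per (variant, seed) and the metric columns
#'   of [compute_metrics()].
#' @export
run_ablation <- function(source, target,
                         variants = c("full", "no_target", "no_global",
                                      "no_domain"),
                         seeds = 21L, model_cfg = model_config(),
                         train_cfg = train_config(),
                         walk_cfg = walk_config()) {
  grid <- tidyr::expand_grid(variant = variants, seed = as.integer(seeds))
  purrr::pmap_dfr(grid, function(variant, seed) {
    tc <- train_cfg
    tc$variant <- variant
    tc$seed <- seed
    fit <- train_damgcn(source, target, model_cfg, tc, walk_cfg)
    dplyr::mutate(evaluate_fit(fit, "target", "test"),
                  variant = variant, seed = seed, .before = 1)
  })
}

#' Export node embeddings for external 2-D projection
#'
#' Writes an embedding matrix and an aligned label file as delimited text,
#' ready for t-SNE/UMAP tooling. `layer = "raw"` exports the original
#' features of a graph; `layer = "fused"` exports the attention-fused
#' final-layer embeddings of a trained model and therefore requires `fit`.
#'
#' @param graph A [labeled_graph()].
#' @param layer `"raw"` or `"fused"`.
#' @param fit A `damgcn_fit` whose stored graph for `graph$domain_tag`
#'   matches `graph`; required for `layer = "fused"`.
#' @param file Output path for the N x d embedding table (CSV).
#' @param labels_file Output path for the aligned one-column label file.
#' @return Invisibly, the exported embedding matrix.
#' @export
export_embeddings <- function(graph, layer = c("raw", "fused"), fit = NULL,
                              file, labels_file) {
  stopifnot(inherits(graph, "labeled_graph"))
  layer <- match.arg(layer)
  if (layer == "raw") {
    M <- graph$features
  } else {
    if (!inherits(fit, "damgcn_fit")) {
      abort("layer = 'fused' requires a trained model in `fit`",
            class = "damgcn_parameter_error")
    }
    M <- fit$embeddings[[graph$domain_tag]]$Z
    if (nrow(M) != nrow(graph$features)) {
      abort("graph does not match the model's stored domain",
            class = "damgcn_dimension_error")
    }
  }
  colnames(M) <- paste0("e", seq_len(ncol(M)))
  write_feature_table(tibble::as_tibble(M), file)
  write_labels(graph$labels, labels_file)
  invisible(M)
}

#' @export
print.damgcn_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<damgcn_fit> variant = %s, %d epochs\n", x$variant,
              nrow(x$trace)))
  cat(sprintf("  source: %d nodes | target: %d nodes | embedding dim %d\n",
              nrow(x$source$features), nrow(x$target$features),
              x$model_config$hidden2))
  cat(sprintf("  final losses: L_S = %.4f, L_DA = %.4f, L_T = %.4f, total = %.4f\n",
              last$loss_source, last$loss_domain, last$loss_target, last$total))
  invisible(x)
}

#' Tidy the per-epoch loss trace of a fitted model
#'
#' @param x A `damgcn_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `loss_source`, `loss_domain`,
#'   `loss_target`, `total`, `lambda`.
#' @export
tidy.damgcn_fit <- function(x, ...) x$trace

#' One-row summary of a fitted model
#'
#' @param x A `damgcn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant, epochs, final loss components, and
#'   target/source test accuracy.
#' @export
glance.damgcn_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(
    variant = x$variant, epochs = nrow(x$trace),
    loss_source = last$loss_source, loss_domain = last$loss_domain,
    loss_target = last$loss_target, total = last$total,
    accuracy_target = evaluate_fit(x, "target", "test")$accuracy,
    accuracy_source = evaluate_fit(x, "source", "test")$accuracy)
}

#' Loss-curve plot of a fitted model
#'
#' @param object A `damgcn_fit`.
#' @param ... Unused.
#' @return A ggplot of the three loss components and the total per epoch.
#' @export
autoplot.damgcn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              c("loss_source", "loss_domain", "loss_target",
                                "total"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Attention-weight plot per node
#'
#' Shows the distribution of the local-channel attention weight per domain:
#' how much each node's fused representation leans on adjacency propagation
#' versus PPMI diffusion.
#'
#' @param fit A `damgcn_fit` trained with the global channel active.
#' @return A ggplot histogram of `att_a` facetted by domain.
#' @export
plot_attention <- function(fit) {
  stopifnot(inherits(fit, "damgcn_fit"))
  if (is.null(fit$embeddings$source$att)) {
    abort("no attention weights: model trained with variant = 'no_global'",
          class = "damgcn_parameter_error")
  }
  df <- dplyr::bind_rows(
    dplyr::mutate(fit$embeddings$source$att, domain = "source"),
    dplyr::mutate(fit$embeddings$target$att, domain = "target"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$att_a)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~domain) +
    ggplot2::labs(x = "local-channel attention weight") +
    ggplot2::theme_minimal()
}
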
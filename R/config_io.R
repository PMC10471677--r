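#' Read a structured run configuration file
#'
#' Parses a YAML file holding any of the sections `model`, `train`, `walk`
#' (each optional; missing keys fall back to the package defaults) and
#' returns ready-made configuration objects. Key names follow the reference
#' hyperparameter table: `epochs`, `k`, `lr`, `nhid1`, `nhid2`, `dropout`,
#' `gamma1`, `gamma2`, `seed` under `train`/`model`, plus `train_fraction`,
#' `variant`, `lambda_mode`, and the walk keys `walks_per_node`,
#' `walk_length`, `window`.
#'
#' ```yaml
#' model: {nhid1: 128, nhid2: 16, dropout: 0.5}
#' train: {epochs: 300, lr: 0.003, k: 6, gamma1: 1, gamma2: 0.8, seed: 21}
#' walk:  {walks_per_node: 10, walk_length: 40, window: 5}
#' ```
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `model` ([model_config()]), `train`
#'   ([train_config()]) and `walk` ([walk_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "damgcn_io_error")
  }
  raw <- yaml::read_yaml(path)
  m <- raw$model %||% list()
  t <- raw$train %||% list()
  w <- raw$walk %||% list()
  pick <- function(lst, key, default) lst[[key]] %||% default
  model <- model_config(
    hidden1 = pick(m, "nhid1", 128), hidden2 = pick(m, "nhid2", 16),
    dropout = pick(m, "dropout", 0.5), n_classes = pick(m, "n_classes", 2))
  train <- train_config(
    epochs = pick(t, "epochs", 300), lr = pick(t, "lr", 0.003),
    k = pick(t, "k", 6), gamma1 = pick(t, "gamma1", 1),
    gamma2 = pick(t, "gamma2", 0.8), seed = pick(t, "seed", 21),
    train_fraction = pick(t, "train_fraction", 0.6),
    variant = pick(t, "variant", "full"),
    lambda_mode = pick(t, "lambda_mode", "corrected"))
  walk <- walk_config(
    walks_per_node = pick(w, "walks_per_node", 10),
    walk_length = pick(w, "walk_length", 40),
    window = pick(w, "window", 5), seed = w$seed)
  list(model = model, train = train, walk = walk)
}

#' Save or restore a trained model checkpoint
#'
#' The checkpoint is a single serialized file holding every weight tensor
#' keyed by its role, the configurations, the variant, and the loss trace —
#' enough to re-score the stored graphs or export embeddings without
#' retraining.
#'
#' @param fit A `damgcn_fit`.
#' @param path Checkpoint path (RDS).
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns the restored `damgcn_fit`.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "damgcn_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "damgcn_fit")) {
    abort("file is not a damgcn checkpoint", class = "damgcn_io_error")
  }
  fit
}
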
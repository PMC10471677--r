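#' Read a delimited node feature table
#'
#' Reads a delimited text file with one row per node (patient) and one numeric
#' column per feature. A header row, when present, supplies column names; node
#' identifiers default to the row order. Every data cell must parse as a
#' number; the first cell that does not is reported by row and column.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter. `NULL` (default) guesses `,` for `.csv` and
#'   tab otherwise.
#' @param header `TRUE`, `FALSE`, or `"auto"` (default): with `"auto"` the
#'   first row is treated as a header when any of its cells fails to parse as
#'   a number.
#' @return A tibble of numeric feature columns, one row per node, in file
#'   order.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(a = c(1, 2), b = c(3.5, 4.5)), tf)
#' read_feature_table(tf)
#' @export
read_feature_table <- function(path, delim = NULL, header = "auto") {
  if (!file.exists(path)) {
    abort(paste0("feature table not found: ", path), class = "damgcn_io_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("empty feature table: ", path), class = "damgcn_io_error")
  }
  cells <- strsplit(lines, delim, fixed = TRUE)
  ncol <- length(cells[[1]])
  bad <- which(lengths(cells) != ncol)
  if (length(bad) > 0) {
    abort(sprintf("ragged feature table: row %d has %d fields, expected %d",
                  bad[1], lengths(cells)[bad[1]], ncol),
          class = "damgcn_io_error")
  }
  parses <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  if (identical(header, "auto")) {
    header <- !all(parses(cells[[1]]))
  }
  col_names <- if (header) {
    nm <- trimws(cells[[1]])
    cells <- cells[-1]
    nm
  } else {
    paste0("V", seq_len(ncol))
  }
  if (length(cells) == 0) {
    abort(paste0("feature table has a header but no data rows: ", path),
          class = "damgcn_io_error")
  }
  mat <- matrix(NA_real_, nrow = length(cells), ncol = ncol,
                dimnames = list(NULL, col_names))
  for (i in seq_along(cells)) {
    vals <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      abort(sprintf(
        "non-numeric cell at data row %d, column %d (%s): '%s'",
        i, j, col_names[j], trimws(cells[[i]][j])),
        class = "damgcn_io_error")
    }
    mat[i, ] <- vals
  }
  tibble::as_tibble(mat)
}

#' Write a node feature table
#'
#' @param features A data frame / tibble of numeric feature columns.
#' @param path Output path.
#' @param delim Field delimiter (default `,`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, delim = ",") {
  if (is.matrix(features) && is.null(colnames(features))) {
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  }
  readr::write_delim(tibble::as_tibble(features), path, delim = delim)
  invisible(path)
}

#' Read a single-column label file aligned to feature rows
#'
#' @param path Path to a one-column delimited text file of integer class
#'   labels in `0..C-1`, one row per node, same order as the feature table.
#' @return An integer vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("label file not found: ", path), class = "damgcn_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty label file", class = "damgcn_io_error")
  if (is.na(suppressWarnings(as.numeric(lines[1])))) lines <- lines[-1]
  y <- suppressWarnings(as.integer(lines))
  if (anyNA(y)) {
    abort(sprintf("non-integer label at row %d: '%s'",
                  which(is.na(y))[1], lines[which(is.na(y))[1]]),
          class = "damgcn_io_error")
  }
  y
}

#' Write labels
#' @param labels Integer vector of class labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' Read an undirected edge list into an adjacency matrix
#'
#' Edge lists on disk use 0-based node indices (two delimited columns); each
#' row is an undirected edge. In memory the package uses 1-based R indexing.
#'
#' @param path Path to a two-column delimited file of 0-based index pairs.
#' @param n_nodes Number of nodes in the graph.
#' @param delim Field delimiter (default any whitespace or comma).
#' @return An `n_nodes` x `n_nodes` binary symmetric adjacency matrix with a
#'   zero diagonal.
#' @export
read_edge_list <- function(path, n_nodes, delim = "[,[:space:]]+") {
  if (!file.exists(path)) {
    abort(paste0("edge list not found: ", path), class = "damgcn_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  A <- matrix(0, n_nodes, n_nodes)
  if (length(lines) == 0) return(A)
  parts <- strsplit(lines, delim)
  for (r in seq_along(parts)) {
    ij <- suppressWarnings(as.integer(parts[[r]][1:2]))
    if (anyNA(ij)) {
      abort(sprintf("unparseable edge at row %d: '%s'", r, lines[r]),
            class = "damgcn_io_error")
    }
    if (any(ij < 0) || any(ij >= n_nodes)) {
      abort(sprintf("edge index out of range at row %d: '%s' (n_nodes = %d)",
                    r, lines[r], n_nodes), class = "damgcn_io_error")
    }
    i <- ij[1] + 1L; j <- ij[2] + 1L
    if (i != j) { A[i, j] <- 1; A[j, i] <- 1 }
  }
  A
}

#' Write an adjacency matrix as a 0-based undirected edge list
#' @param adjacency Symmetric adjacency matrix.
#' @param path Output path.
#' @param delim Delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(adjacency, path, delim = "\t") {
  idx <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
  lines <- sprintf("%d%s%d", idx[, 1] - 1L, delim, idx[, 2] - 1L)
  writeLines(lines, path)
  invisible(path)
}

#' Build a k-nearest-neighbour patient similarity graph
#'
#' Connects each node to its `k` nearest neighbours by feature distance (self
#' excluded) and symmetrizes the edge set by union, yielding an undirected
#' binary graph. Distance ties are broken by lower node index, so the graph is
#' deterministic.
#'
#' @param features Numeric matrix or data frame, one row per node.
#' @param k Number of neighbours per node (default 6). Must satisfy `k < N`.
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param standardize If `TRUE`, z-score each feature column before computing
#'   distances (default `FALSE`).
#' @return An N x N binary symmetric adjacency matrix with zero diagonal.
#' @examples
#' X <- matrix(c(0, 1, 2, 3, 10), ncol = 1)
#' build_knn_graph(X, k = 1)
#' @export
build_knn_graph <- function(features, k = 6, metric = "euclidean",
                            standardize = FALSE) {
  X <- as_feature_matrix(features)
  n <- nrow(X)
  if (k >= n || k < 1) {
    abort(sprintf("k must satisfy 1 <= k < N; got k = %d with N = %d", k, n),
          class = "damgcn_parameter_error")
  }
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
    X <- X[, , drop = FALSE]
  }
  D <- as.matrix(dist(X, method = metric))
  diag(D) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # order() is stable: equal distances resolve to the lower node index
    nn <- order(D[i, ])[seq_len(k)]
    A[i, nn] <- 1
  }
  A <- pmax(A, t(A))  # union symmetrization
  diag(A) <- 0
  A
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Adds self-loops and rescales: with `A~ = A + I` and degree
#' `D~_ii = sum_j A~_ij`, returns the propagation operator
#' `D~^{-1/2} A~ D~^{-1/2}` used by the local-consistency graph convolution.
#'
#' @param adjacency Symmetric non-negative N x N matrix with zero diagonal.
#' @return A [normalized_operator()] with `flavor = "adjacency"`.
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2)
#' normalize_adjacency(A)$matrix  # all entries 1/2
#' @export
normalize_adjacency <- function(adjacency) {
  A <- as.matrix(adjacency)
  stopifnot(nrow(A) == ncol(A))
  if (any(A < 0)) abort("adjacency must be non-negative", class = "damgcn_parameter_error")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))  # self-loop guarantees positive degree
  op <- dinv * At * rep(dinv, each = nrow(At))
  normalized_operator(op, "adjacency")
}

#' Construct a normalized propagation operator
#'
#' @param matrix N x N finite numeric matrix, ready for graph convolution.
#' @param flavor Either `"adjacency"` (local channel) or `"ppmi"` (global
#'   channel).
#' @return An object of class `normalized_operator`.
#' @export
normalized_operator <- function(matrix, flavor = c("adjacency", "ppmi")) {
  flavor <- match.arg(flavor)
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) {
    abort("normalized operator must be finite", class = "damgcn_parameter_error")
  }
  structure(list(matrix = matrix, flavor = flavor),
            class = "normalized_operator")
}

#' @export
print.normalized_operator <- function(x, ...) {
  cat(sprintf("<normalized_operator> flavor = %s, %d x %d\n",
              x$flavor, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Bundle one domain's graph, features and labels
#'
#' A labeled graph holds one domain of the transfer problem: an undirected
#' patient similarity graph, the node feature matrix, and binary (or
#' multiclass) node outcomes. When no adjacency is supplied, a KNN graph is
#' built from the features.
#'
#' @param features Numeric matrix or data frame (N rows, d features).
#' @param labels Integer vector of length N with classes in `0..C-1`.
#' @param adjacency Optional N x N symmetric non-negative matrix with zero
#'   diagonal; built with [build_knn_graph()] when `NULL`.
#' @param domain_tag `"source"` or `"target"`.
#' @param k Neighbours for KNN construction when `adjacency` is `NULL`.
#' @param metric,standardize Passed to [build_knn_graph()].
#' @return An object of class `labeled_graph` with elements `adjacency`,
#'   `features` (matrix), `labels`, `domain_tag`.
#' @export
labeled_graph <- function(features, labels, adjacency = NULL,
                          domain_tag = c("source", "target"), k = 6,
                          metric = "euclidean", standardize = FALSE) {
  domain_tag <- match.arg(domain_tag)
  X <- as_feature_matrix(features)
  if (anyNA(X)) abort("features contain missing values", class = "damgcn_parameter_error")
  if (ncol(X) < 1) abort("need at least one feature", class = "damgcn_parameter_error")
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) {
    abort(sprintf("labels length (%d) must equal number of nodes (%d)",
                  length(labels), nrow(X)), class = "damgcn_parameter_error")
  }
  if (any(labels < 0)) abort("labels must be in 0..C-1", class = "damgcn_parameter_error")
  if (is.null(adjacency)) {
    adjacency <- build_knn_graph(X, k = k, metric = metric,
                                 standardize = standardize)
  }
  A <- as.matrix(adjacency)
  if (!isTRUE(all.equal(A, t(A)))) {
    abort("adjacency must be symmetric", class = "damgcn_parameter_error")
  }
  if (any(diag(A) != 0)) {
    abort("adjacency diagonal must be zero before self-loop augmentation",
          class = "damgcn_parameter_error")
  }
  if (any(A < 0)) abort("adjacency must be non-negative", class = "damgcn_parameter_error")
  structure(list(adjacency = A, features = X, labels = labels,
                 domain_tag = domain_tag),
            class = "labeled_graph")
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("<labeled_graph> %s: %d nodes, %d edges, %d features, %d classes\n",
              x$domain_tag, nrow(x$features), sum(x$adjacency != 0) / 2,
              ncol(x$features), length(unique(x$labels))))
  invisible(x)
}

#' Write a labeled graph as plain-text files
#'
#' Writes `features.csv`, `labels.txt` and `edges.tsv` (0-based undirected
#' edge list) into a directory, so synthetic and real data flow through the
#' same on-disk representation.
#'
#' @param graph A [labeled_graph()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_domain <- function(graph, dir) {
  stopifnot(inherits(graph, "labeled_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(graph$features, file.path(dir, "features.csv"))
  write_labels(graph$labels, file.path(dir, "labels.txt"))
  write_edge_list(graph$adjacency, file.path(dir, "edges.tsv"))
  invisible(dir)
}

#' Read a labeled graph written by [write_domain()]
#'
#' @param dir Directory containing `features.csv`, `labels.txt` and
#'   `edges.tsv`.
#' @param domain_tag `"source"` or `"target"`.
#' @return A [labeled_graph()].
#' @export
read_domain <- function(dir, domain_tag = c("source", "target")) {
  feats <- read_feature_table(file.path(dir, "features.csv"))
  y <- read_labels(file.path(dir, "labels.txt"))
  A <- read_edge_list(file.path(dir, "edges.tsv"), n_nodes = nrow(feats))
  labeled_graph(feats, y, adjacency = A, domain_tag = match.arg(domain_tag))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_feature_matrix <- function(features) {
  X <- if (is.matrix(features)) features else as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  X
}
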
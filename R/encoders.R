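# Feature encoders ---------------------------------------------------------
#
# Three text-feature encoders feed the survival model: the 14 finding
# labels passed through unchanged, transformer-style average pooling of
# token embeddings, and a two-layer graph convolutional network (GCN) over
# the radiology finding concept graph whose nodes are initialized by a 1-D
# convolution over the report's token embeddings.

#' Average-pool token embeddings
#'
#' Column-wise arithmetic mean of an m x d token-embedding matrix, the
#' aggregate latent representation of a report.
#'
#' @param tokens Numeric matrix, one row per token (m >= 1).
#' @return Numeric vector of length d.
#' @export
pool_token_embeddings <- function(tokens) {
  if (!is.matrix(tokens) || nrow(tokens) < 1L) {
    stop_input("`tokens` must be a matrix with at least one row")
  }
  if (any(!is.finite(tokens))) stop_input("`tokens` contains non-finite entries")
  colMeans(tokens)
}

#' Construct a radiology concept graph
#'
#' @param nodes Character vector of finding names (N nodes).
#' @param edges List of length-2 vectors naming connected findings (or a
#'   2-column matrix of node names/indices).
#' @return Object of class `concept_graph`: list with `adjacency`
#'   (symmetric binary N x N matrix, zero diagonal) and `node_names`.
#' @export
concept_graph <- function(nodes, edges = list()) {
  N <- length(nodes)
  if (N < 1 || anyDuplicated(nodes)) stop_input("`nodes` must be distinct names")
  A <- matrix(0, N, N, dimnames = list(nodes, nodes))
  for (e in edges) {
    if (length(e) != 2) stop_input("each edge must connect exactly two nodes")
    i <- if (is.character(e)) match(e, nodes) else as.integer(e)
    if (anyNA(i) || any(i < 1 | i > N)) {
      stop_input("edge refers to unknown node: %s", paste(e, collapse = "--"))
    }
    if (i[1] == i[2]) stop_input("self-loops are added during normalization, not in A")
    A[i[1], i[2]] <- 1
    A[i[2], i[1]] <- 1
  }
  structure(list(adjacency = A, node_names = nodes), class = "concept_graph")
}

#' Read a concept graph from JSON
#'
#' Expects the schema `{"nodes": [...], "edges": [[a, b], ...]}`.
#' @param path Path to a JSON file.
#' @return A `concept_graph`.
#' @export
read_concept_graph <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(g$edges)) {
    if (is.matrix(g$edges)) asplit(g$edges, 1) else g$edges
  } else list()
  concept_graph(g$nodes, edges)
}

#' The default radiology finding graph
#'
#' CheXpert-style clinical hierarchy over the 14 finding nodes, shipped as
#' an editable JSON file in the package's `extdata`.
#' @return A `concept_graph` with 14 nodes.
#' @export
default_concept_graph <- function() {
  read_concept_graph(icusurv_extdata("concept_graph.json"))
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf("Concept graph: %d nodes, %d edges\n",
              length(x$node_names), sum(x$adjacency) / 2))
  invisible(x)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes A_hat = D^(-1/2) (A + I) D^(-1/2), where D is the diagonal
#' degree matrix of A + I. Precomputed once per graph; the edgeless graph
#' normalizes to the identity.
#'
#' @param graph A `concept_graph` (or a symmetric binary matrix).
#' @return Symmetric N x N matrix A_hat with eigenvalues in \[-1, 1\].
#' @export
normalize_adjacency <- function(graph) {
  A <- if (inherits(graph, "concept_graph")) graph$adjacency else as.matrix(graph)
  if (!isSymmetric(unname(A))) stop_input("adjacency matrix must be symmetric")
  if (!all(A %in% c(0, 1))) stop_input("adjacency matrix must be binary")
  if (any(diag(A) != 0)) stop_input("adjacency must have a zero diagonal")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * tcrossprod(dinv)
}

#' GCN parameters
#'
#' Seeded random initialization of the graph encoder: 1-D convolution
#' weights (one kernel per graph node) used to initialize node features
#' from token embeddings, and the two propagation layers' weight matrices.
#' These parameters are fixed at feature-extraction time (the graph
#' encoder is not trained jointly with the survival model).
#'
#' @param n_nodes Number of graph nodes N (14 for the default graph).
#' @param kernel_size 1-D convolution kernel size k (default 3).
#' @param token_dim Embedding dimension d of the token matrix.
#' @param hidden_dim Width of the first propagation layer.
#' @param output_dim Per-node output features of the second layer.
#' @param seed Integer seed.
#' @return Object of class `gcn_params`.
#' @export
gcn_params <- function(n_nodes = 14L, kernel_size = 3L, token_dim = 768L,
                       hidden_dim = 64L, output_dim = 4L, seed = 1L) {
  stopifnot(n_nodes >= 1, kernel_size >= 1, token_dim >= 1,
            hidden_dim >= 1, output_dim >= 1)
  set.seed(seed)
  structure(list(
    n_nodes = as.integer(n_nodes),
    kernel_size = as.integer(kernel_size),
    token_dim = as.integer(token_dim),
    hidden_dim = as.integer(hidden_dim),
    output_dim = as.integer(output_dim),
    conv_weights = matrix(stats::rnorm(n_nodes * kernel_size, sd = 1 / sqrt(kernel_size)),
                          n_nodes, kernel_size),
    conv_bias = numeric(n_nodes),
    W0 = matrix(stats::rnorm(token_dim * hidden_dim, sd = sqrt(2 / token_dim)),
                token_dim, hidden_dim),
    b0 = numeric(hidden_dim),
    W1 = matrix(stats::rnorm(hidden_dim * output_dim, sd = sqrt(2 / hidden_dim)),
                hidden_dim, output_dim),
    b1 = numeric(output_dim)
  ), class = "gcn_params")
}

#' Initialize GCN node features from token embeddings
#'
#' Applies a 1-D convolution along the token axis (kernel size k, one
#' output channel per graph node, "valid" padding, weights shared across
#' embedding dimensions) and averages over the convolved positions, so
#' each node's initial feature row aggregates the hidden features of all
#' tokens in the report: H0\[c, \] = mean_p sum_j w\[c, j\] X\[p + j - 1, \].
#'
#' @param tokens m x d token-embedding matrix with m >= kernel_size.
#' @param params A [gcn_params()].
#' @return N x d matrix H0.
#' @export
init_node_features <- function(tokens, params) {
  stopifnot(inherits(params, "gcn_params"))
  if (!is.matrix(tokens)) stop_input("`tokens` must be a matrix")
  m <- nrow(tokens)
  k <- params$kernel_size
  if (m < k) {
    stop_input(paste0(
      "report has %d token(s) but the convolution kernel size is %d; ",
      "pad the token matrix to at least k rows (e.g. repeat the last ",
      "token) before encoding"), m, k)
  }
  P <- m - k + 1L
  # windowed means: M[j, ] = mean over positions p of X[p + j - 1, ]
  cs <- rbind(0, apply(tokens, 2, cumsum))
  M <- (cs[(P + 1):(P + k), , drop = FALSE] - cs[1:k, , drop = FALSE]) / P
  params$conv_weights %*% M + params$conv_bias
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Two-layer GCN propagation
#'
#' H1 = ReLU(A_hat H0 W0 + b0); Z = softmax(A_hat H1 W1 + b1), with the
#' softmax taken across each node's row of output features.
#'
#' @param H0 N x d node-feature matrix from [init_node_features()].
#' @param A_hat Normalized adjacency from [normalize_adjacency()].
#' @param params A [gcn_params()].
#' @return N x output_dim matrix Z; each row sums to 1.
#' @export
gcn_forward <- function(H0, A_hat, params) {
  stopifnot(inherits(params, "gcn_params"))
  if (!is.matrix(H0) || !is.matrix(A_hat)) stop_input("`H0` and `A_hat` must be matrices")
  if (nrow(A_hat) != ncol(A_hat)) stop_input("`A_hat` must be square")
  if (nrow(H0) != nrow(A_hat)) {
    stop_input("`H0` has %d rows but `A_hat` is %d x %d",
               nrow(H0), nrow(A_hat), ncol(A_hat))
  }
  if (ncol(H0) != nrow(params$W0)) {
    stop_input("`H0` has %d columns but `W0` expects %d",
               ncol(H0), nrow(params$W0))
  }
  H1 <- pmax(A_hat %*% H0 %*% params$W0 +
               matrix(params$b0, nrow(H0), params$hidden_dim, byrow = TRUE), 0)
  Zpre <- A_hat %*% H1 %*% params$W1 +
    matrix(params$b1, nrow(H0), params$output_dim, byrow = TRUE)
  row_softmax(Zpre)
}

#' Encode a subject's text features
#'
#' The three text-feature modes of the survival model: `labels` returns
#' the 14 finding labels unchanged; `transformer` average-pools the token
#' embeddings (length d vector); `gcn` runs the graph encoder and returns
#' the flattened node-output matrix (length N * output_dim, rows
#' concatenated in node order).
#'
#' @param record list with fields `labels` (length-14 binary vector) and,
#'   for the embedding modes, `token_embeddings` (m x d matrix).
#' @param mode `"labels"`, `"transformer"`, or `"gcn"`.
#' @param params A [gcn_params()] (gcn mode only).
#' @param graph A `concept_graph` (gcn mode only; default graph if NULL).
#' @return Numeric feature vector.
#' @export
encode_text <- function(record, mode = c("labels", "transformer", "gcn"),
                        params = NULL, graph = NULL) {
  mode <- match.arg(mode)
  if (mode == "labels") {
    labels <- as.numeric(record$labels)
    if (length(labels) != 14) stop_input("`record$labels` must have 14 entries")
    return(labels)
  }
  if (is.null(record$token_embeddings)) {
    stop_input("mode '%s' requires `record$token_embeddings`", mode)
  }
  if (mode == "transformer") {
    return(pool_token_embeddings(record$token_embeddings))
  }
  params <- params %||% gcn_params(token_dim = ncol(record$token_embeddings))
  graph <- graph %||% default_concept_graph()
  A_hat <- normalize_adjacency(graph)
  H0 <- init_node_features(record$token_embeddings, params)
  Z <- gcn_forward(H0, A_hat, params)
  as.vector(t(Z))
}

# Encode text features for a whole cohort (n x p matrix). For gcn /
# transformer modes, token matrices are regenerated from the cohort's
# per-subject embedding seeds.
encode_cohort_text <- function(cohort, mode, params = NULL, graph = NULL) {
  stopifnot(inherits(cohort, "icu_cohort"))
  n <- nrow(cohort$data)
  if (mode == "labels") return(cohort_label_matrix(cohort))
  if (mode == "transformer") {
    if (is.null(cohort$text_pooled)) stop_input("cohort carries no embeddings")
    return(cohort$text_pooled)
  }
  params <- params %||% gcn_params(token_dim = cohort$config$token_dim)
  graph <- graph %||% default_concept_graph()
  A_hat <- normalize_adjacency(graph)
  out <- matrix(0, n, params$n_nodes * params$output_dim)
  for (i in seq_len(n)) {
    tok <- token_embeddings(cohort, i)
    Z <- gcn_forward(init_node_features(tok, params), A_hat, params)
    out[i, ] <- as.vector(t(Z))
  }
  out
}
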
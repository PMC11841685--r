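test_that("average pooling is the column mean", {
  one <- matrix(rnorm(5), 1, 5)
  expect_equal(pool_token_embeddings(one), drop(one))
  same <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(pool_token_embeddings(same), c(1, 2, 3))
  set.seed(1)
  X <- matrix(rnorm(35), 7, 5)
  want <- vapply(1:5, function(j) {
    acc <- 0
    for (i in 1:7) acc <- acc + X[i, j]
    acc / 7
  }, numeric(1))
  expect_equal(pool_token_embeddings(X), want, tolerance = 1e-12)
  # linearity
  expect_equal(pool_token_embeddings(3.7 * X), 3.7 * pool_token_embeddings(X),
               tolerance = 1e-12)
  expect_error(pool_token_embeddings(X[0, , drop = FALSE]), "at least one row")
})

test_that("adjacency normalization matches hand computations", {
  # edgeless graph: A~ = I, D = I, A_hat = I
  g0 <- concept_graph(letters[1:4])
  expect_equal(unname(normalize_adjacency(g0)), diag(4))
  # two nodes, one edge: D = diag(2, 2), all entries 0.5
  g2 <- concept_graph(c("a", "b"), list(c("a", "b")))
  expect_equal(unname(normalize_adjacency(g2)), matrix(0.5, 2, 2))
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("normalized adjacency is symmetric with spectrum in [-1, 1]", {
  set.seed(7)
  for (rep in 1:10) {
    N <- sample(3:12, 1)
    A <- matrix(0, N, N)
    edges <- which(upper.tri(A), arr.ind = TRUE)
    on <- edges[runif(nrow(edges)) < 0.4, , drop = FALSE]
    A[on] <- 1
    A <- A + t(A)
    Ah <- normalize_adjacency(A)
    expect_equal(Ah, t(Ah), tolerance = 1e-12)
    ev <- eigen(Ah, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
    # input never mutated; recomputation identical
    expect_equal(normalize_adjacency(A), Ah)
  }
})

test_that("node initialization is the stated 1-D convolution", {
  p <- gcn_params(n_nodes = 3, kernel_size = 1, token_dim = 6, seed = 2)
  p$conv_weights <- matrix(1, 3, 1)    # unit channels
  p$conv_bias <- numeric(3)
  tok <- matrix(rnorm(6), 1, 6)
  H0 <- init_node_features(tok, p)
  for (i in 1:3) expect_equal(H0[i, ], drop(tok), tolerance = 1e-12)

  # random instances against the sliding-window loop oracle
  for (seed in 1:50) {
    set.seed(seed)
    m <- sample(4:15, 1); d <- sample(2:6, 1); k <- sample(1:3, 1)
    N <- sample(2:5, 1)
    pp <- gcn_params(n_nodes = N, kernel_size = k, token_dim = d, seed = seed)
    tok <- matrix(rnorm(m * d), m, d)
    expect_equal(init_node_features(tok, pp),
                 conv_oracle(tok, pp$conv_weights, pp$conv_bias),
                 tolerance = 1e-8)
  }
  expect_error(init_node_features(matrix(0, 2, 4),
                                  gcn_params(kernel_size = 3, token_dim = 4)),
               "pad")
})

test_that("two-layer propagation matches hand-multiplied matrices", {
  # 2-node toy on the single-edge graph, scalar features
  p <- gcn_params(n_nodes = 2, kernel_size = 1, token_dim = 1,
                  hidden_dim = 1, output_dim = 2, seed = 3)
  p$W0 <- matrix(1.5); p$b0 <- 0.2
  p$W1 <- matrix(c(0.7, -0.3), 1, 2); p$b1 <- c(0.1, -0.1)
  Ah <- matrix(0.5, 2, 2)
  H0 <- matrix(c(1, -2), 2, 1)
  # hand arithmetic: AH0 = (-0.5, -0.5); H1 = relu(1.5*AH0 + 0.2) = (0, 0)
  # Z row logits = b1 -> softmax(c(0.1, -0.1))
  Z <- gcn_forward(H0, Ah, p)
  want_row <- exp(c(0.1, -0.1)) / sum(exp(c(0.1, -0.1)))
  expect_equal(Z[1, ], want_row, tolerance = 1e-10)
  expect_equal(Z[2, ], want_row, tolerance = 1e-10)

  # identity propagation under nonnegative H0
  pid <- gcn_params(n_nodes = 3, kernel_size = 1, token_dim = 2,
                    hidden_dim = 2, output_dim = 2, seed = 4)
  pid$W0 <- diag(2); pid$b0 <- c(0, 0)
  H0 <- matrix(abs(rnorm(6)), 3, 2)
  H1 <- pmax(diag(3) %*% H0 %*% pid$W0, 0)
  expect_equal(H1, H0)
})

test_that("softmax rows are simplex-normalized and shapes propagate", {
  set.seed(5)
  p <- gcn_params(n_nodes = 14, kernel_size = 3, token_dim = 24,
                  hidden_dim = 8, output_dim = 4, seed = 5)
  Ah <- normalize_adjacency(default_concept_graph())
  tok <- matrix(rnorm(30 * 24), 30, 24)
  Z <- gcn_forward(init_node_features(tok, p), Ah, p)
  expect_identical(dim(Z), c(14L, 4L))
  expect_equal(unname(rowSums(Z)), rep(1, 14), tolerance = 1e-12)
  expect_error(gcn_forward(matrix(0, 5, 24), Ah, p), "rows")
})

test_that("permuting graph nodes permutes outputs identically", {
  set.seed(6)
  N <- 6
  A <- matrix(0, N, N)
  A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1; A[4, 5] <- A[5, 4] <- 1
  p <- gcn_params(n_nodes = N, kernel_size = 1, token_dim = 3,
                  hidden_dim = 4, output_dim = 2, seed = 6)
  H0 <- matrix(rnorm(N * 3), N, 3)
  Z <- gcn_forward(H0, normalize_adjacency(A), p)
  perm <- c(3, 1, 4, 6, 2, 5)
  P <- diag(N)[perm, ]
  Zp <- gcn_forward(H0[perm, ], normalize_adjacency(P %*% A %*% t(P)), p)
  expect_equal(Zp, Z[perm, ], tolerance = 1e-10)
})

test_that("encode_text dispatches the three feature modes", {
  labels <- c(1, rep(0, 13))
  expect_equal(encode_text(list(labels = labels), "labels"), labels)
  tok <- matrix(rnorm(40 * 16), 40, 16)
  expect_equal(encode_text(list(token_embeddings = tok), "transformer"),
               colMeans(tok))
  p <- gcn_params(n_nodes = 14, kernel_size = 3, token_dim = 16,
                  hidden_dim = 4, output_dim = 2, seed = 8)
  z <- encode_text(list(token_embeddings = tok), "gcn", params = p)
  expect_length(z, 14 * 2)
  Z <- gcn_forward(init_node_features(tok, p),
                   normalize_adjacency(default_concept_graph()), p)
  expect_equal(z, as.vector(t(Z)), tolerance = 1e-12)
  expect_error(encode_text(list(labels = labels), "transformer"),
               "token_embeddings")
})

test_that("the default concept graph round-trips from JSON", {
  g <- default_concept_graph()
  expect_identical(g$node_names, finding_labels())
  A <- g$adjacency
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_equal(A["lung_opacity", "edema"], 1)
  expect_equal(A["enlarged_cardiomediastinum", "cardiomegaly"], 1)
  expect_equal(A["normal", "lung_opacity"], 0)
})
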
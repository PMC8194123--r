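test_that("graph convolution reduces to known closed forms", {
  n <- 4; d <- 3
  X <- matrix(rnorm(n * d), n)
  I_graph <- diag(n)
  # identity graph, identity weights, zero bias: plain elementwise tanh
  expect_equal(graph_conv_layer(I_graph, X, diag(d), activation = "tanh"),
               tanh(X))
  # uniform features under any row-stochastic W are a fixed point
  W <- matrix(runif(n * n), n)
  W <- W / rowSums(W)
  Xu <- matrix(rep(c(1, -2, 0.5), each = n), n)
  expect_equal(graph_conv_layer(W, Xu, diag(d), activation = "linear"), Xu,
               tolerance = 1e-12)
})

test_that("graph convolution equals brute-force neighbour aggregation", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    d <- sample(2:5, 1)
    dp <- sample(2:4, 1)
    A <- matrix(runif(n * n), n)
    A <- A / rowSums(A)
    X <- matrix(rnorm(n * d), n)
    W <- matrix(rnorm(d * dp), d)
    b <- rnorm(dp)
    got <- graph_conv_layer(A, X, W, b, activation = "tanh")
    # double-loop oracle
    expected <- matrix(0, n, dp)
    for (i in 1:n) {
      agg <- numeric(d)
      for (j in 1:n) agg <- agg + A[i, j] * X[j, ]
      expected[i, ] <- tanh(agg %*% W + b)
    }
    expect_equal(got, expected, tolerance = 1e-6)
  }
})

test_that("autoencoder backpropagation matches numerical gradients", {
  set.seed(8)
  n <- 5
  X <- matrix(rnorm(n * 4), n)
  Fp <- matrix(rbinom(n * 6, 1, 0.5), n)
  A <- matrix(runif(n * n), n)
  A <- A / rowSums(A)
  params <- list(
    list(W = matrix(rnorm(4 * 3, sd = 0.5), 4), b = rnorm(3), act = "tanh"),
    list(W = matrix(rnorm(3 * 6, sd = 0.5), 3), b = rnorm(6), act = "sigmoid")
  )
  loss_at <- function(p) {
    gcanddi:::bce_loss(gcanddi:::mlp_forward(p, X, A)$final, Fp)
  }
  cache <- gcanddi:::mlp_forward(params, X, A)
  bk <- gcanddi:::mlp_backward(params, cache,
                               gcanddi:::bce_dtop(cache$final, Fp), A)
  eps <- 1e-6
  for (l in 1:2) {
    for (idx in sample(length(params[[l]]$W), 5)) {
      pp <- params; pp[[l]]$W[idx] <- pp[[l]]$W[idx] + eps
      pm <- params; pm[[l]]$W[idx] <- pm[[l]]$W[idx] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(bk$grads[[l]]$W[idx], num, tolerance = 1e-5)
    }
    pp <- params; pp[[l]]$b[1] <- pp[[l]]$b[1] + eps
    pm <- params; pm[[l]]$b[1] <- pm[[l]]$b[1] - eps
    expect_equal(bk$grads[[l]]$b[1], (loss_at(pp) - loss_at(pm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("GCAN training reduces the loss and is seed-deterministic", {
  st <- tiny_study()
  cfg <- tiny_gcan_config(epochs = 60)
  m1 <- train_gcan(st$drugs, st$graph, cfg)
  m2 <- train_gcan(st$drugs, st$graph, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  expect_lt(tail(m1$loss_trace, 1), m1$loss_trace[1])
})

test_that("noise-free fingerprints are reconstructed almost perfectly", {
  cl <- clean_study()
  cfg <- tiny_gcan_config(epochs = 400, seed = 17)
  m <- train_gcan(cl$drugs, cl$graph, cfg)
  expect_gt(gcanddi:::reconstruction_accuracy(m, cl$drugs), 0.95)
})

test_that("embedding is deterministic and respects functional equality", {
  st <- tiny_study()
  m <- train_gcan(st$drugs, st$graph, tiny_gcan_config(epochs = 40))
  e1 <- embed_drugs(m, st$drugs)
  expect_identical(e1, embed_drugs(m, st$drugs))
  expect_equal(ncol(e1) - 1L, 16L)  # embedding width = last encoder dim
  # duplicate a drug: identical signature + identical graph row =>
  # identical embedding row
  drugs2 <- st$drugs
  drugs2[2, -1] <- drugs2[1, -1]
  g2 <- build_similarity_graph(drugs2, k = 10)
  e2 <- embed_drugs(m, drugs2, g2)
  expect_equal(unlist(e2[1, -1]), unlist(e2[2, -1]), ignore_attr = TRUE)
})

test_that("embedded features preserve the planted class structure", {
  cl <- clean_study()
  m <- train_gcan(cl$drugs, cl$graph, tiny_gcan_config(epochs = 200, seed = 23))
  emb <- gcanddi:::feature_matrix(embed_drugs(m, cl$drugs))
  cos <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  n <- nrow(emb)
  same <- c(); diff <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      v <- cos(emb[i, ], emb[j, ])
      if (cl$drugs$class[i] == cl$drugs$class[j]) same <- c(same, v)
      else diff <- c(diff, v)
    }
  }
  expect_gt(mean(same), mean(diff))
})

test_that("a GCAN on the identity graph reproduces the autoencoder baseline", {
  st <- tiny_study()
  cfg <- tiny_gcan_config(epochs = 30, dropout = 0)
  n <- nrow(st$drugs)
  ident <- diag(n)
  dimnames(ident) <- list(st$drugs$drug_id, st$drugs$drug_id)
  g_ident <- structure(list(drug_ids = st$drugs$drug_id, weights = ident),
                       class = "similarity_graph")
  m_graph <- train_gcan(st$drugs, g_ident, cfg)
  m_base <- train_autoencoder_baseline(st$drugs, cfg)
  expect_equal(m_graph$loss_trace, m_base$loss_trace, tolerance = 1e-12)
  expect_lt(tail(m_base$loss_trace, 1), m_base$loss_trace[1])
})

test_that("disabling the L2 penalty never hurts the training loss", {
  st <- tiny_study()
  m_reg <- train_gcan(st$drugs, st$graph,
                      tiny_gcan_config(epochs = 80, l2_rate = 1e-5))
  m_free <- train_gcan(st$drugs, st$graph,
                       tiny_gcan_config(epochs = 80, l2_rate = 0))
  expect_lte(tail(m_free$loss_trace, 1), tail(m_reg$loss_trace, 1) + 1e-8)
})

test_that("embedding restores the structure correlation lost to noise", {
  # moderate-noise instance over 3 seeds: GCAN-embedded profile
  # correlation with structure beats the raw-signature correlation
  for (seed in 1:3) {
    cfg <- tiny_config(expr_noise_sd = 2, seed = seed)
    drugs <- simulate_drugs(cfg)
    graph <- build_similarity_graph(drugs, k = 10)
    m <- train_gcan(drugs, graph, tiny_gcan_config(epochs = 100, seed = seed))
    emb <- embed_drugs(m, drugs)
    tbl <- structure_correlation_table(
      drugs,
      list(original = signature_features(drugs), gcan = emb)
    )
    med <- tapply(tbl$r, tbl$feature_kind, median, na.rm = TRUE)
    expect_gt(med[["gcan"]], med[["original"]])
  }
})
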
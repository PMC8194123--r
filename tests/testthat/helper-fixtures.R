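# Shared fixtures, built in code and memoized so expensive objects are
# created once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small, moderately noisy planted-class study: 60 drugs, 3 classes.
tiny_config <- function(expr_noise_sd = 1, bit_flip_rate = 0.05, seed = 7,
                        n_drugs = 60, n_classes = 3, n_types = 4,
                        n_pairs = 400) {
  simulation_config(
    n_drugs = n_drugs, n_classes = n_classes, fp_bits = 64, sig_dim = 50,
    bit_flip_rate = bit_flip_rate, expr_noise_sd = expr_noise_sd,
    n_types = n_types, n_pairs = n_pairs, seed = seed
  )
}

tiny_study <- function() {
  memo("tiny_study", {
    cfg <- tiny_config()
    drugs <- simulate_drugs(cfg)
    pairs <- suppressMessages(simulate_ddis(drugs, cfg))
    graph <- build_similarity_graph(drugs, k = 10)
    list(cfg = cfg, drugs = drugs, pairs = pairs, graph = graph)
  })
}

# Noise-free counterpart: classes are perfectly separable by construction.
clean_study <- function() {
  memo("clean_study", {
    cfg <- tiny_config(expr_noise_sd = 0, bit_flip_rate = 0, seed = 11)
    drugs <- simulate_drugs(cfg)
    pairs <- suppressMessages(simulate_ddis(drugs, cfg))
    graph <- build_similarity_graph(drugs, k = 10)
    list(cfg = cfg, drugs = drugs, pairs = pairs, graph = graph)
  })
}

# Scaled-down architecture configs matched to the 50-dim fixtures.
tiny_gcan_config <- function(epochs = 150, seed = 3, ...) {
  gcan_config(
    encoder_dims = c(50, 32, 16), decoder_dims = c(16, 32, 64),
    learning_rate = 1e-2, epochs = epochs, seed = seed, ...
  )
}

tiny_lstm_config <- function(epochs = 120, seed = 5, ...) {
  lstm_config(
    units_per_layer = 32, learning_rate = 3e-3, epochs = epochs,
    batch_size = 64, dropout = 0.2, seed = seed, ...
  )
}

tiny_dnn_config <- function(epochs = 120, seed = 5, ...) {
  dnn_config(
    hidden_dims = c(64, 32), learning_rate = 3e-3, epochs = epochs,
    batch_size = 64, dropout = 0.2, seed = seed, ...
  )
}

signature_features <- function(drugs) {
  drugs[c("drug_id", grep("^g[0-9]+$", names(drugs), value = TRUE))]
}

gcan_features_tiny <- function() {
  memo("gcan_features_tiny", {
    st <- tiny_study()
    model <- train_gcan(st$drugs, st$graph, tiny_gcan_config())
    embed_drugs(model, st$drugs)
  })
}

extdata <- function(name) {
  system.file("extdata", name, package = "gcanddi", mustWork = TRUE)
}
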
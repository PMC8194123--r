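# Graph convolutional autoencoder (GCAN): encodes 977-dim transcriptome
# signatures into a low-dimensional embedding by propagating each drug's
# signature over the structure-similarity graph, under a loss that asks the
# decoder to reconstruct the drug's Morgan fingerprint. The non-graph
# autoencoder baseline is the same network with identity propagation.

#' GCAN architecture and training configuration
#'
#' Defaults follow the reference architecture: encoder 977-640-512 and
#' decoder 512-640-1024, tanh on every layer except the final decoder layer
#' (sigmoid, so outputs are per-bit probabilities for the cross-entropy
#' fingerprint loss), learning rate 1e-4, L2 rate 1e-5, dropout 0.3 on
#' hidden layers during training.
#'
#' @param encoder_dims Integer vector of encoder layer widths, input first.
#' @param decoder_dims Integer vector of decoder layer widths; the first
#'   entry must equal the last encoder width and the last entry the
#'   fingerprint length.
#' @param learning_rate Adam learning rate.
#' @param l2_rate Coefficient of the L2 weight penalty.
#' @param dropout Hidden-layer dropout rate during training.
#' @param epochs Maximum full-batch epochs.
#' @param patience,min_delta Early stopping on the training-loss plateau:
#'   stop after `patience` epochs without an improvement of at least
#'   `min_delta`. Set `patience = Inf` to disable.
#' @param seed Integer seed controlling initialization and dropout.
#' @return An object of class `gcan_config`.
#' @export
gcan_config <- function(encoder_dims = c(977, 640, 512),
                        decoder_dims = c(512, 640, 1024),
                        learning_rate = 1e-4,
                        l2_rate = 1e-5,
                        dropout = 0.3,
                        epochs = 500,
                        patience = 20,
                        min_delta = 1e-5,
                        seed = 1L) {
  if (length(encoder_dims) < 2 || length(decoder_dims) < 2) {
    abort("Encoder and decoder each need at least an input and an output width.")
  }
  if (utils::tail(encoder_dims, 1) != decoder_dims[1]) {
    abort("First decoder width must equal the last encoder width (the embedding).")
  }
  structure(
    list(
      encoder_dims = as.integer(encoder_dims),
      decoder_dims = as.integer(decoder_dims),
      learning_rate = check_nonneg(learning_rate, "learning_rate"),
      l2_rate = check_nonneg(l2_rate, "l2_rate"),
      dropout = check_prob(dropout, "dropout"),
      epochs = check_count(epochs, "epochs"),
      patience = patience,
      min_delta = check_nonneg(min_delta, "min_delta"),
      seed = as.integer(seed)
    ),
    class = "gcan_config"
  )
}

# Resolve a similarity_graph (or bare matrix, or NULL for identity
# propagation) against the drug ordering of the feature matrix.
resolve_graph <- function(graph, drug_ids) {
  if (is.null(graph)) return(NULL)
  w <- if (inherits(graph, "similarity_graph")) graph$weights else as.matrix(graph)
  ids <- if (inherits(graph, "similarity_graph")) graph$drug_ids else rownames(w)
  if (!is.null(ids) && !identical(as.character(ids), as.character(drug_ids))) {
    if (!all(drug_ids %in% ids)) {
      abort("Graph does not cover all drugs in the feature table.")
    }
    w <- w[drug_ids, drug_ids, drop = FALSE]
    rs <- rowSums(w)
    if (any(abs(rs - 1) > 1e-8)) {
      abort("Graph row order mismatch cannot be fixed by reordering: rows no longer sum to 1.")
    }
  }
  w
}

#' Single graph convolution layer
#'
#' Computes `activation(A %*% features %*% W + b)`: each node's features are
#' replaced by the edge-weighted combination of its own and its most similar
#' neighbours' features, linearly transformed and passed through the
#' activation.
#'
#' @param graph A `similarity_graph` (or bare row-stochastic matrix).
#' @param features Numeric n x d matrix, rows ordered as the graph.
#' @param W d x d' weight matrix.
#' @param b Length-d' bias vector (default zeros).
#' @param activation `"tanh"`, `"sigmoid"` or `"linear"`.
#' @return n x d' matrix.
#' @export
graph_conv_layer <- function(graph, features, W, b = NULL,
                             activation = "tanh") {
  features <- as.matrix(features)
  A <- resolve_graph(graph, rownames(features) %||% seq_len(nrow(features)))
  if (!is.null(A) && nrow(A) != nrow(features)) {
    abort("Graph size does not match the number of feature rows.")
  }
  if (nrow(W) != ncol(features)) {
    abort(sprintf("Weight matrix expects %d input columns, features have %d.",
                  nrow(W), ncol(features)))
  }
  b <- b %||% numeric(ncol(W))
  M <- if (is.null(A)) features else A %*% features
  act_forward(sweep(M %*% W, 2, b, "+"), activation)
}

# Build the 4-layer (in general, length-driven) parameter stack from config.
gcan_init_params <- function(config) {
  dims <- c(config$encoder_dims, config$decoder_dims[-1])
  n_layers <- length(dims) - 1L
  lapply(seq_len(n_layers), function(l) {
    list(
      W = glorot(dims[l], dims[l + 1L]),
      b = numeric(dims[l + 1L]),
      act = if (l == n_layers) "sigmoid" else "tanh"
    )
  })
}

gcan_train_engine <- function(X, Fp, A, config, kind) {
  if (config$encoder_dims[1] != ncol(X)) {
    abort(sprintf("Encoder input width (%d) must equal the signature length (%d).",
                  config$encoder_dims[1], ncol(X)))
  }
  if (utils::tail(config$decoder_dims, 1) != ncol(Fp)) {
    abort(sprintf("Decoder output width (%d) must equal the fingerprint length (%d).",
                  utils::tail(config$decoder_dims, 1), ncol(Fp)))
  }
  n_enc <- length(config$encoder_dims) - 1L
  # one seed stream for both kinds, so an identity-graph GCAN reproduces
  # the autoencoder baseline exactly under equal seeds
  with_seed(derive_seed(config$seed, "gcan-train"), {
    params <- gcan_init_params(config)
    state <- adam_init(params)
    hidden_dims <- lapply(params[-length(params)],
                          function(p) c(nrow(X), ncol(p$W)))
    trace <- numeric(0)
    best <- Inf
    stall <- 0L
    for (epoch in seq_len(config$epochs)) {
      masks <- dropout_masks_for(hidden_dims, config$dropout)
      cache <- mlp_forward(params, X, A, masks)
      loss <- bce_loss(cache$final, Fp) + l2_penalty(params, config$l2_rate)
      if (!is.finite(loss)) {
        abort(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch))
      }
      trace <- c(trace, loss)
      bk <- mlp_backward(params, cache, bce_dtop(cache$final, Fp), A, masks)
      upd <- adam_update(params, bk$grads, state, config$learning_rate,
                         epoch, config$l2_rate)
      params <- upd$params
      state <- upd$state
      if (best - loss > config$min_delta) {
        best <- loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (is.finite(config$patience) && stall >= config$patience) break
      }
    }
    structure(
      list(
        params = params, config = config, n_encoder_layers = n_enc,
        graph_weights = A, drug_ids = rownames(X), loss_trace = trace,
        feature_kind = kind
      ),
      class = "gcan_model"
    )
  })
}

#' Train the graph convolutional autoencoder
#'
#' Full-batch training that minimizes the mean per-bit binary cross-entropy
#' between the decoder's sigmoid output and each drug's Morgan fingerprint,
#' plus an L2 weight penalty. Every layer propagates over the similarity
#' graph; dropout is applied to hidden activations during training only.
#' Reproducible: identical drugs/graph/config give identical loss traces.
#'
#' @param drugs A drug table with `g*` signature and `fp*` fingerprint
#'   columns (see [simulate_drugs()] or [read_drug_table()]).
#' @param graph A `similarity_graph` over the same drugs, from
#'   [build_similarity_graph()].
#' @param config A [gcan_config()].
#' @return A `gcan_model` holding the trained weights, per-epoch training
#'   loss trace, and the graph used (needed at embedding time).
#' @export
train_gcan <- function(drugs, graph, config = gcan_config()) {
  X <- signature_matrix(drugs)
  Fp <- fp_matrix(drugs)
  A <- resolve_graph(graph, rownames(X))
  if (is.null(A) || nrow(A) != nrow(X)) {
    abort("`graph` must cover exactly the drugs in `drugs`.")
  }
  gcan_train_engine(X, Fp, A, config, kind = "gcan")
}

#' Train the non-graph autoencoder baseline
#'
#' Identical architecture, loss and training schedule to [train_gcan()] but
#' with identity propagation (no neighbour mixing): each drug's signature is
#' encoded independently. Equivalent to a GCAN trained on an identity graph.
#'
#' @inheritParams train_gcan
#' @return A `gcan_model` with `feature_kind = "autoencoder"`.
#' @export
train_autoencoder_baseline <- function(drugs, config = gcan_config()) {
  X <- signature_matrix(drugs)
  Fp <- fp_matrix(drugs)
  gcan_train_engine(X, Fp, A = NULL, config, kind = "autoencoder")
}

#' Embed drugs with a trained model
#'
#' Runs the encoder half (dropout disabled) and returns the top encoder
#' layer: one row per drug, embedding width equal to the last encoder
#' dimension (512 by default).
#'
#' @param model A trained `gcan_model`.
#' @param drugs The drug table to embed (defaults to the training drugs'
#'   ordering; must carry `g*` columns).
#' @param graph Similarity graph to propagate over; defaults to the graph
#'   stored in the model. Ignored by autoencoder-baseline models.
#' @return A tibble: `drug_id` plus embedding columns `e1..eK`.
#' @export
embed_drugs <- function(model, drugs, graph = NULL) {
  stopifnot(inherits(model, "gcan_model"))
  X <- signature_matrix(drugs)
  A <- if (model$feature_kind == "autoencoder") {
    NULL
  } else if (is.null(graph)) {
    if (!identical(rownames(X), model$drug_ids)) {
      abort("Drug set differs from training; supply the matching `graph`.")
    }
    model$graph_weights
  } else {
    resolve_graph(graph, rownames(X))
  }
  enc <- model$params[seq_len(model$n_encoder_layers)]
  emb <- mlp_forward(enc, X, A, dropout_masks = NULL)$final
  rownames(emb) <- rownames(X)
  matrix_to_feature_tbl(emb)
}

# Fingerprint reconstruction accuracy (mean per-bit 0.5-thresholded match),
# used by tests and diagnostics.
reconstruction_accuracy <- function(model, drugs) {
  X <- signature_matrix(drugs)
  Fp <- fp_matrix(drugs)
  p <- mlp_forward(model$params, X, model$graph_weights, NULL)$final
  mean((p > 0.5) == (Fp > 0.5))
}

#' @export
print.gcan_model <- function(x, ...) {
  cat(sprintf(
    "<gcan_model> kind=%s, %d drugs, embedding dim %d, %d epochs, final loss %.4f\n",
    x$feature_kind, length(x$drug_ids),
    ncol(x$params[[x$n_encoder_layers]]$W),
    length(x$loss_trace), utils::tail(x$loss_trace, 1)
  ))
  invisible(x)
}

#' Tidy the training-loss trace of an embedding model
#'
#' @param x A `gcan_model`.
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss`.
#' @method tidy gcan_model
#' @export
tidy.gcan_model <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of an embedding model fit
#'
#' @param x A `gcan_model`.
#' @param ... Unused.
#' @return A one-row tibble: feature kind, drugs, embedding width, epochs
#'   run, initial and final training loss.
#' @method glance gcan_model
#' @export
glance.gcan_model <- function(x, ...) {
  tibble(
    feature_kind = x$feature_kind,
    n_drugs = length(x$drug_ids),
    embedding_dim = ncol(x$params[[x$n_encoder_layers]]$W),
    epochs_run = length(x$loss_trace),
    initial_loss = x$loss_trace[1],
    final_loss = utils::tail(x$loss_trace, 1)
  )
}

#' Plot the training-loss trace
#'
#' @param object A `gcan_model`.
#' @param ... Unused.
#' @return A ggplot of loss versus epoch.
#' @method autoplot gcan_model
#' @export
autoplot.gcan_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Epoch", y = "Training loss (BCE + L2)",
      title = sprintf("%s reconstruction loss", object$feature_kind)
    ) +
    ggplot2::theme_minimal()
}
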
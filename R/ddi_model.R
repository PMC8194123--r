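# DDI-type classifiers over drug-pair features. The primary model treats an
# ordered pair as a length-2 sequence of drug feature vectors fed to a
# stacked LSTM; the baseline concatenates the two vectors into a DNN. Both
# share a sigmoid multi-label output head trained with per-type binary
# cross-entropy (one interaction record contributes a one-hot row; the head
# itself is multi-label so co-occurring types are representable).

#' LSTM classifier configuration
#'
#' Defaults follow the reference model: two layers of 400 units,
#' forget-gate bias initialized at 0.7, learning rate 1e-4, dropout 0.5,
#' batch size 256, L2 rate 1e-5.
#'
#' @param n_layers Number of stacked LSTM layers.
#' @param units_per_layer Hidden width of every layer.
#' @param forget_bias Initial additive bias of the forget gate.
#' @param learning_rate Adam learning rate.
#' @param dropout Dropout rate on each layer's outward connections
#'   (training only; the recurrent path is not dropped).
#' @param batch_size Minibatch size.
#' @param l2_rate L2 weight-penalty coefficient.
#' @param epochs Maximum training epochs.
#' @param val_fraction Fraction of training pairs held out for early
#'   stopping (0 disables; the plateau rule then watches training loss).
#' @param patience,min_delta Early-stopping plateau rule.
#' @param seed Integer seed (initialization, shuffling, dropout, split).
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(n_layers = 2,
                        units_per_layer = 400,
                        forget_bias = 0.7,
                        learning_rate = 1e-4,
                        dropout = 0.5,
                        batch_size = 256,
                        l2_rate = 1e-5,
                        epochs = 300,
                        val_fraction = 0.1,
                        patience = 20,
                        min_delta = 1e-5,
                        seed = 1L) {
  structure(
    list(
      n_layers = check_count(n_layers, "n_layers"),
      units_per_layer = check_count(units_per_layer, "units_per_layer"),
      forget_bias = check_nonneg(forget_bias, "forget_bias"),
      learning_rate = check_nonneg(learning_rate, "learning_rate"),
      dropout = check_prob(dropout, "dropout"),
      batch_size = check_count(batch_size, "batch_size"),
      l2_rate = check_nonneg(l2_rate, "l2_rate"),
      epochs = check_count(epochs, "epochs"),
      val_fraction = check_prob(val_fraction, "val_fraction"),
      patience = patience,
      min_delta = check_nonneg(min_delta, "min_delta"),
      seed = as.integer(seed)
    ),
    class = "lstm_config"
  )
}

#' DNN baseline configuration
#'
#' The baseline concatenates the two drugs' feature vectors and feeds the
#' result through a fully connected network with the same multi-label head
#' and training schedule as the LSTM.
#'
#' @param hidden_dims Integer vector of hidden-layer widths.
#' @param activation Hidden activation (`"relu"` or `"tanh"`).
#' @inheritParams lstm_config
#' @return An object of class `dnn_config`.
#' @export
dnn_config <- function(hidden_dims = c(512, 256),
                       activation = "relu",
                       learning_rate = 1e-4,
                       dropout = 0.5,
                       batch_size = 256,
                       l2_rate = 1e-5,
                       epochs = 300,
                       val_fraction = 0.1,
                       patience = 20,
                       min_delta = 1e-5,
                       seed = 1L) {
  structure(
    list(
      hidden_dims = as.integer(hidden_dims),
      activation = match.arg(activation, c("relu", "tanh")),
      learning_rate = check_nonneg(learning_rate, "learning_rate"),
      dropout = check_prob(dropout, "dropout"),
      batch_size = check_count(batch_size, "batch_size"),
      l2_rate = check_nonneg(l2_rate, "l2_rate"),
      epochs = check_count(epochs, "epochs"),
      val_fraction = check_prob(val_fraction, "val_fraction"),
      patience = patience,
      min_delta = check_nonneg(min_delta, "min_delta"),
      seed = as.integer(seed)
    ),
    class = "dnn_config"
  )
}

#' Stack a drug pair's feature vectors into a length-2 sequence
#'
#' @param features A feature tibble (`drug_id` + numeric columns), e.g. from
#'   [embed_drugs()].
#' @param pair A list or one-row data frame with `drug_a` and `drug_b`.
#' @return A 2 x d matrix: row 1 is `drug_a`'s vector, row 2 `drug_b`'s.
#' @export
make_pair_sequence <- function(features, pair) {
  fm <- feature_matrix(features)
  ids <- c(pair$drug_a[1], pair$drug_b[1])
  missing <- setdiff(ids, rownames(fm))
  if (length(missing) > 0) {
    abort(sprintf("Drug id(s) not in the feature table: %s",
                  paste(missing, collapse = ", ")))
  }
  out <- fm[ids, , drop = FALSE]
  rownames(out) <- c("drug_a", "drug_b")
  out
}

# Look up the two N x d feature blocks for a pair table, with a helpful
# error naming unknown ids.
pair_feature_blocks <- function(pairs, fm) {
  missing <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), rownames(fm))
  if (length(missing) > 0) {
    abort(sprintf("Drug id(s) not in the feature table: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  list(
    X1 = fm[pairs$drug_a, , drop = FALSE],
    X2 = fm[pairs$drug_b, , drop = FALSE]
  )
}

#' Design matrices for classical multi-label baselines
#'
#' The adapter seam for off-the-shelf multi-label classifiers (random
#' forest, kNN variants, ...): the concatenated pair feature matrix and the
#' binary label indicator matrix, ready to hand to any library that accepts
#' `(X, Y)`.
#'
#' @param pairs Tibble of `drug_a`, `drug_b`, `type_label`.
#' @param features Feature tibble (`drug_id` + numeric columns).
#' @return A list with `X` (n_pairs x 2d) and `Y` (n_pairs x n_types 0/1,
#'   columns named by type).
#' @export
pair_design_matrix <- function(pairs, features) {
  fm <- feature_matrix(features)
  blocks <- pair_feature_blocks(pairs, fm)
  vocab <- sort(unique(pairs$type_label))
  Y <- outer(pairs$type_label, vocab, "==") * 1
  colnames(Y) <- vocab
  list(X = cbind(blocks$X1, blocks$X2), Y = Y)
}

one_hot_labels <- function(labels, vocab) {
  Y <- outer(labels, vocab, "==") * 1
  colnames(Y) <- vocab
  Y
}

# --- LSTM forward / backward ----------------------------------------------

lstm_init_params <- function(d_in, config) {
  u <- config$units_per_layer
  lapply(seq_len(config$n_layers), function(l) {
    din <- if (l == 1) d_in else u
    b <- numeric(4 * u)
    b[(u + 1):(2 * u)] <- config$forget_bias  # forget-gate slice
    list(W = glorot(din, 4 * u), U = glorot(u, 4 * u), b = b)
  })
}

split_gates <- function(a, u) {
  list(
    i = sigmoid(a[, 1:u, drop = FALSE]),
    f = sigmoid(a[, (u + 1):(2 * u), drop = FALSE]),
    g = tanh(a[, (2 * u + 1):(3 * u), drop = FALSE]),
    o = sigmoid(a[, (3 * u + 1):(4 * u), drop = FALSE])
  )
}

# Forward over the 2-step sequence for all stacked layers. Dropout masks
# (one per layer, applied to that layer's h1/h2 outward outputs) are NULL at
# inference.
lstm_forward <- function(layers, head, X1, X2, masks = NULL) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    p <- layers[[l]]
    u <- length(p$b) / 4
    a1 <- sweep(X1 %*% p$W, 2, p$b, "+")
    g1 <- split_gates(a1, u)
    c1 <- g1$i * g1$g                    # c0 = 0
    tc1 <- tanh(c1)
    h1 <- g1$o * tc1
    a2 <- sweep(X2 %*% p$W + h1 %*% p$U, 2, p$b, "+")
    g2 <- split_gates(a2, u)
    c2 <- g2$f * c1 + g2$i * g2$g
    tc2 <- tanh(c2)
    h2 <- g2$o * tc2
    m <- if (is.null(masks)) NULL else masks[[l]]
    h1_out <- if (is.null(m)) h1 else h1 * m$m1
    h2_out <- if (is.null(m)) h2 else h2 * m$m2
    caches[[l]] <- list(
      X1 = X1, X2 = X2, g1 = g1, g2 = g2, c1 = c1, tc1 = tc1, tc2 = tc2,
      h1 = h1, h2 = h2, mask = m
    )
    X1 <- h1_out
    X2 <- h2_out
  }
  logits <- sweep(X2 %*% head$W, 2, head$b, "+")
  list(caches = caches, top_h2 = X2, probs = sigmoid(logits))
}

# Exact backpropagation through time (2 steps) and depth. dLogits is the
# gradient at the pre-sigmoid head output.
lstm_backward <- function(layers, head, fwd, dLogits) {
  gHead <- list(W = crossprod(fwd$top_h2, dLogits), b = colSums(dLogits))
  dh2 <- tcrossprod(dLogits, head$W)
  dh1 <- 0
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    cc <- fwd$caches[[l]]
    p <- layers[[l]]
    if (!is.null(cc$mask)) {
      dh2 <- dh2 * cc$mask$m2
      dh1 <- dh1 * cc$mask$m1
    }
    g1 <- cc$g1; g2 <- cc$g2
    # t = 2
    do2 <- dh2 * cc$tc2
    dc2 <- dh2 * g2$o * (1 - cc$tc2^2)
    di2 <- dc2 * g2$g
    df2 <- dc2 * cc$c1
    dg2 <- dc2 * g2$i
    dc1 <- dc2 * g2$f
    da2 <- cbind(
      di2 * g2$i * (1 - g2$i), df2 * g2$f * (1 - g2$f),
      dg2 * (1 - g2$g^2), do2 * g2$o * (1 - g2$o)
    )
    dh1 <- dh1 + tcrossprod(da2, p$U)
    # t = 1 (c0 = 0, so the forget path carries no gradient)
    do1 <- dh1 * cc$tc1
    dc1 <- dc1 + dh1 * g1$o * (1 - cc$tc1^2)
    di1 <- dc1 * g1$g
    dg1 <- dc1 * g1$i
    da1 <- cbind(
      di1 * g1$i * (1 - g1$i), matrix(0, nrow(da2), ncol(da2) / 4),
      dg1 * (1 - g1$g^2), do1 * g1$o * (1 - g1$o)
    )
    grads[[l]] <- list(
      W = crossprod(cc$X1, da1) + crossprod(cc$X2, da2),
      U = crossprod(cc$h1, da2),
      b = colSums(da1) + colSums(da2)
    )
    dh2 <- tcrossprod(da2, p$W)
    dh1 <- tcrossprod(da1, p$W)
  }
  list(layers = grads, head = gHead)
}

# --- shared minibatch trainer ---------------------------------------------

# One trainer drives both architectures; `engine` abstracts forward/backward
# so the schedule (shuffling, Adam, early stopping) is identical.
train_pair_classifier <- function(pairs, features, config, kind,
                                  feature_kind = "unknown") {
  stopifnot(is.data.frame(pairs),
            all(c("drug_a", "drug_b", "type_label") %in% names(pairs)))
  fm <- feature_matrix(features)
  blocks <- pair_feature_blocks(pairs, fm)
  vocab <- sort(unique(as.character(pairs$type_label)))
  Y <- one_hot_labels(as.character(pairs$type_label), vocab)
  n <- nrow(pairs)
  d <- ncol(fm)
  with_seed(derive_seed(config$seed, paste0(kind, "-train")), {
    if (kind == "lstm") {
      layers <- lstm_init_params(d, config)
      u <- config$units_per_layer
      head <- list(W = glorot(u, length(vocab)), b = numeric(length(vocab)))
    } else {
      dims <- c(2 * d, config$hidden_dims, length(vocab))
      layers <- lapply(seq_len(length(dims) - 1L), function(l) {
        list(
          W = glorot(dims[l], dims[l + 1L]), b = numeric(dims[l + 1L]),
          act = if (l == length(dims) - 1L) "sigmoid" else config$activation
        )
      })
      head <- NULL
    }
    all_params <- if (kind == "lstm") c(layers, list(head)) else layers
    state <- adam_init(all_params)

    n_val <- if (config$val_fraction > 0 && n >= 10) {
      max(1L, floor(config$val_fraction * n))
    } else {
      0L
    }
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)

    eval_loss <- function(idx) {
      if (kind == "lstm") {
        fwd <- lstm_forward(layers, head, blocks$X1[idx, , drop = FALSE],
                            blocks$X2[idx, , drop = FALSE])
        bce_loss(fwd$probs, Y[idx, , drop = FALSE])
      } else {
        X <- cbind(blocks$X1[idx, , drop = FALSE], blocks$X2[idx, , drop = FALSE])
        bce_loss(mlp_forward(layers, X)$final, Y[idx, , drop = FALSE])
      }
    }

    trace <- numeric(0)
    val_trace <- numeric(0)
    best <- Inf
    best_snapshot <- list(layers = layers, head = head)
    stall <- 0L
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (bt in batches) {
        Yb <- Y[bt, , drop = FALSE]
        if (kind == "lstm") {
          masks <- NULL
          if (config$dropout > 0) {
            masks <- lapply(seq_along(layers), function(l) {
              u <- config$units_per_layer
              list(
                m1 = matrix((runif(length(bt) * u) >= config$dropout) /
                              (1 - config$dropout), length(bt), u),
                m2 = matrix((runif(length(bt) * u) >= config$dropout) /
                              (1 - config$dropout), length(bt), u)
              )
            })
          }
          fwd <- lstm_forward(layers, head, blocks$X1[bt, , drop = FALSE],
                              blocks$X2[bt, , drop = FALSE], masks)
          loss <- bce_loss(fwd$probs, Yb) +
            l2_penalty(c(layers, list(head)), config$l2_rate)
          if (!is.finite(loss)) {
            abort(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch))
          }
          dLogits <- (fwd$probs - Yb) / length(Yb)
          bk <- lstm_backward(layers, head, fwd, dLogits)
          step <- step + 1L
          upd <- adam_update(c(layers, list(head)),
                             c(bk$layers, list(bk$head)),
                             state, config$learning_rate, step, config$l2_rate)
          layers <- upd$params[seq_along(layers)]
          head <- upd$params[[length(upd$params)]]
          state <- upd$state
        } else {
          Xb <- cbind(blocks$X1[bt, , drop = FALSE], blocks$X2[bt, , drop = FALSE])
          masks <- if (config$dropout > 0) {
            dropout_masks_for(
              lapply(layers[-length(layers)],
                     function(p) c(length(bt), ncol(p$W))),
              config$dropout
            )
          }
          cache <- mlp_forward(layers, Xb, NULL, masks)
          loss <- bce_loss(cache$final, Yb) + l2_penalty(layers, config$l2_rate)
          if (!is.finite(loss)) {
            abort(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch))
          }
          bk <- mlp_backward(layers, cache, bce_dtop(cache$final, Yb), NULL, masks)
          step <- step + 1L
          upd <- adam_update(layers, bk$grads, state, config$learning_rate,
                             step, config$l2_rate)
          layers <- upd$params
          state <- upd$state
        }
        epoch_loss <- epoch_loss + loss * length(bt)
      }
      trace <- c(trace, epoch_loss / length(train_idx))
      watch <- if (n_val > 0) eval_loss(val_idx) else utils::tail(trace, 1)
      val_trace <- c(val_trace, watch)
      if (best - watch > config$min_delta) {
        best <- watch
        best_snapshot <- list(layers = layers, head = head)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (is.finite(config$patience) && stall >= config$patience) break
      }
    }
    structure(
      list(
        kind = kind, layers = best_snapshot$layers, head = best_snapshot$head,
        vocab = vocab, config = config, feature_kind = feature_kind,
        loss_trace = trace, watch_trace = val_trace,
        feature_dim = d
      ),
      class = "ddi_classifier"
    )
  })
}

#' Train the LSTM pair-sequence DDI classifier
#'
#' Feeds each ordered pair as the length-2 sequence (drug_a's features, then
#' drug_b's) through stacked LSTM layers; the final hidden state drives a
#' sigmoid multi-label head trained with per-type binary cross-entropy and
#' an L2 penalty, using Adam with seeded minibatch shuffling. A fraction of
#' the training pairs is held out for early stopping; the returned model is
#' the best snapshot under that watch loss.
#'
#' @param pairs Tibble of ordered pairs: `drug_a`, `drug_b`, `type_label`.
#' @param features Feature tibble (`drug_id` + numeric columns), any of the
#'   raw-signature, autoencoder or GCAN feature spaces.
#' @param config An [lstm_config()].
#' @param feature_kind Tag recorded on the model (`"original"`,
#'   `"autoencoder"`, `"gcan"`, ...).
#' @return A `ddi_classifier`.
#' @export
train_lstm <- function(pairs, features, config = lstm_config(),
                       feature_kind = "unknown") {
  stopifnot(inherits(config, "lstm_config"))
  train_pair_classifier(pairs, features, config, "lstm", feature_kind)
}

#' Train the concatenation DNN baseline
#'
#' Same task, head, loss and schedule as [train_lstm()], but the pair is
#' represented as the concatenation `[f(drug_a), f(drug_b)]` through a
#' fully connected network, discarding the sequence structure.
#'
#' @inheritParams train_lstm
#' @param config A [dnn_config()].
#' @return A `ddi_classifier`.
#' @export
train_dnn_baseline <- function(pairs, features, config = dnn_config(),
                               feature_kind = "unknown") {
  stopifnot(inherits(config, "dnn_config"))
  train_pair_classifier(pairs, features, config, "dnn", feature_kind)
}

#' Score drug pairs with a trained classifier
#'
#' @param object A `ddi_classifier`.
#' @param features Feature tibble covering every drug in `pairs` (same
#'   feature space the classifier was trained on).
#' @param pairs Tibble with `drug_a`, `drug_b` (a `type_label` column, if
#'   present, is carried through untouched).
#' @param threshold Decision threshold on the per-type sigmoid scores; every
#'   type scoring at or above it is predicted, and when none does the
#'   arg-max type is predicted (so every pair gets at least one label).
#' @param ... Unused.
#' @return A tibble: `drug_a`, `drug_b`, (`type_label`,) `pred_label`
#'   (arg-max type), `pred_labels` (list-column, decoded label set) and one
#'   `score_<type>` column per type.
#' @export
predict.ddi_classifier <- function(object, features, pairs, threshold = 0.5, ...) {
  fm <- feature_matrix(features)
  blocks <- pair_feature_blocks(pairs, fm)
  probs <- if (object$kind == "lstm") {
    lstm_forward(object$layers, object$head, blocks$X1, blocks$X2)$probs
  } else {
    mlp_forward(object$layers, cbind(blocks$X1, blocks$X2))$final
  }
  colnames(probs) <- object$vocab
  top <- object$vocab[max.col(probs, ties.method = "first")]
  decoded <- lapply(seq_len(nrow(probs)), function(i) {
    hit <- object$vocab[probs[i, ] >= threshold]
    if (length(hit) == 0) top[i] else hit
  })
  out <- tibble(drug_a = pairs$drug_a, drug_b = pairs$drug_b)
  if ("type_label" %in% names(pairs)) out$type_label <- pairs$type_label
  out$pred_label <- top
  out$pred_labels <- decoded
  score_tbl <- as_tibble(probs, .name_repair = ~ paste0("score_", .x))
  dplyr::bind_cols(out, score_tbl)
}

# Binary prediction matrix over a vocabulary from a prediction tibble.
prediction_matrix <- function(pred, vocab) {
  P <- matrix(0L, nrow(pred), length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(nrow(pred))) {
    hit <- intersect(pred$pred_labels[[i]], vocab)
    P[i, hit] <- 1L
  }
  P
}

#' @export
print.ddi_classifier <- function(x, ...) {
  cat(sprintf(
    "<ddi_classifier> %s on %s features, %d types, %d epochs (final loss %.4f)\n",
    toupper(x$kind), x$feature_kind, length(x$vocab),
    length(x$loss_trace), utils::tail(x$loss_trace, 1)
  ))
  invisible(x)
}

#' Tidy a classifier's training trace
#'
#' @param x A `ddi_classifier`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss` and `watch_loss` (validation
#'   loss, or training loss when no validation split was used).
#' @method tidy ddi_classifier
#' @export
tidy.ddi_classifier <- function(x, ...) {
  tibble(
    epoch = seq_along(x$loss_trace),
    train_loss = x$loss_trace,
    watch_loss = x$watch_trace
  )
}

#' One-row summary of a trained classifier
#'
#' @param x A `ddi_classifier`.
#' @param ... Unused.
#' @return A one-row tibble of architecture, feature kind, label count and
#'   final losses.
#' @method glance ddi_classifier
#' @export
glance.ddi_classifier <- function(x, ...) {
  tibble(
    method = x$kind,
    feature_kind = x$feature_kind,
    n_types = length(x$vocab),
    feature_dim = x$feature_dim,
    epochs_run = length(x$loss_trace),
    final_train_loss = utils::tail(x$loss_trace, 1),
    best_watch_loss = min(x$watch_trace)
  )
}
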
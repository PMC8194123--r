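test_that("pair sequences preserve order and report unknown drugs", {
  feats <- tibble::tibble(drug_id = c("d1", "d2"), f1 = c(1, 3), f2 = c(2, 4))
  s <- make_pair_sequence(feats, list(drug_a = "d1", drug_b = "d2"))
  expect_equal(unname(s), rbind(c(1, 2), c(3, 4)))
  r <- make_pair_sequence(feats, list(drug_a = "d2", drug_b = "d1"))
  expect_equal(unname(r), unname(s[2:1, ]))
  expect_false(isTRUE(all.equal(s, r)))
  expect_error(make_pair_sequence(feats, list(drug_a = "d1", drug_b = "zz")),
               "zz")
})

test_that("the classical-baseline design matrices have the contracted shape", {
  st <- tiny_study()
  feats <- signature_features(st$drugs)
  dm <- pair_design_matrix(st$pairs, feats)
  expect_equal(ncol(dm$X), 2 * (ncol(feats) - 1))
  expect_equal(dim(dm$Y), c(nrow(st$pairs), length(unique(st$pairs$type_label))))
  expect_true(all(rowSums(dm$Y) == 1))
})

test_that("LSTM backpropagation matches numerical gradients", {
  set.seed(19)
  N <- 4; d <- 3; u <- 5; L <- 2
  cfg <- lstm_config(n_layers = 2, units_per_layer = u, seed = 1)
  layers <- gcanddi:::with_seed(1, gcanddi:::lstm_init_params(d, cfg))
  head <- gcanddi:::with_seed(2, list(W = gcanddi:::glorot(u, L), b = rnorm(L)))
  X1 <- matrix(rnorm(N * d), N)
  X2 <- matrix(rnorm(N * d), N)
  Y <- matrix(rbinom(N * L, 1, 0.5), N)
  loss_at <- function(ly, hd) {
    fwd <- gcanddi:::lstm_forward(ly, hd, X1, X2)
    gcanddi:::bce_loss(fwd$probs, Y)
  }
  fwd <- gcanddi:::lstm_forward(layers, head, X1, X2)
  bk <- gcanddi:::lstm_backward(layers, head, fwd, (fwd$probs - Y) / length(Y))
  eps <- 1e-6
  for (l in 1:2) {
    for (nm in c("W", "U", "b")) {
      for (idx in sample(length(layers[[l]][[nm]]), 4)) {
        lp <- layers; lp[[l]][[nm]][idx] <- lp[[l]][[nm]][idx] + eps
        lm <- layers; lm[[l]][[nm]][idx] <- lm[[l]][[nm]][idx] - eps
        num <- (loss_at(lp, head) - loss_at(lm, head)) / (2 * eps)
        expect_equal(bk$layers[[l]][[nm]][idx], num, tolerance = 1e-5)
      }
    }
  }
  hp <- head; hp$W[1] <- hp$W[1] + eps
  hm <- head; hm$W[1] <- hm$W[1] - eps
  expect_equal(bk$head$W[1], (loss_at(layers, hp) - loss_at(layers, hm)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("both classifiers fit a separable planted dataset to macro-F1 ~ 1", {
  cl <- clean_study()
  feats <- signature_features(cl$drugs)
  for (trainer in list(
    function() train_lstm(cl$pairs, feats, tiny_lstm_config(epochs = 200)),
    function() train_dnn_baseline(cl$pairs, feats, tiny_dnn_config(epochs = 200))
  )) {
    fit <- trainer()
    pred <- predict(fit, feats, cl$pairs)
    mm <- gcanddi:::metrics_from_predictions(pred, fit$vocab)
    expect_gte(mm$macro_f1, 0.99)
    # decoded labels recover the planted labels on ~all training pairs
    expect_gte(mean(pred$pred_label == cl$pairs$type_label), 0.99)
  }
})

test_that("training and prediction are seed-deterministic", {
  st <- tiny_study()
  feats <- gcan_features_tiny()
  cfg <- tiny_lstm_config(epochs = 30)
  f1 <- train_lstm(st$pairs, feats, cfg)
  f2 <- train_lstm(st$pairs, feats, cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  p1 <- predict(f1, feats, st$pairs)
  expect_identical(p1, predict(f2, feats, st$pairs))
  expect_identical(p1, predict(f1, feats, st$pairs))
})

test_that("a single-type dataset collapses to that type", {
  cl <- clean_study()
  feats <- signature_features(cl$drugs)
  one <- dplyr::filter(cl$pairs, type_label == cl$pairs$type_label[1])
  fit <- train_lstm(one, feats, tiny_lstm_config(epochs = 30))
  pred <- predict(fit, feats, one)
  expect_true(all(pred$pred_label == one$type_label[1]))
})

test_that("sub-threshold scores fall back to the arg-max label", {
  st <- tiny_study()
  feats <- gcan_features_tiny()
  fit <- train_lstm(st$pairs, feats, tiny_lstm_config(epochs = 10))
  # an impossible threshold forces the fallback everywhere
  pred <- predict(fit, feats, st$pairs, threshold = 1.1)
  expect_true(all(lengths(pred$pred_labels) == 1))
  expect_identical(unlist(pred$pred_labels), pred$pred_label)
})

test_that("inference is invariant to pair order within a batch", {
  st <- tiny_study()
  feats <- gcan_features_tiny()
  fit <- train_lstm(st$pairs, feats, tiny_lstm_config(epochs = 20))
  perm <- rev(seq_len(nrow(st$pairs)))
  p_fwd <- predict(fit, feats, st$pairs)
  p_rev <- predict(fit, feats, st$pairs[perm, ])
  score_cols <- grep("^score_", names(p_fwd), value = TRUE)
  expect_equal(as.data.frame(p_rev[rev(seq_len(nrow(p_rev))), score_cols]),
               as.data.frame(p_fwd[score_cols]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("swapping pair order changes the LSTM input sequence, not the drugs", {
  st <- tiny_study()
  feats <- gcan_features_tiny()
  fit <- train_lstm(st$pairs, feats, tiny_lstm_config(epochs = 20))
  fwd <- st$pairs[1, ]
  rev_pair <- tibble::tibble(drug_a = fwd$drug_b, drug_b = fwd$drug_a)
  s1 <- predict(fit, feats, fwd)
  s2 <- predict(fit, feats, rev_pair)
  score_cols <- grep("^score_", names(s1), value = TRUE)
  expect_false(isTRUE(all.equal(as.numeric(s1[1, score_cols]),
                                as.numeric(s2[1, score_cols]))))
})
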
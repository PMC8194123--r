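brute_force_macro <- function(truth, pred) {
  # independent per-type recount straight from the definitions
  n_types <- ncol(truth)
  rec <- prec <- numeric(n_types)
  for (i in seq_len(n_types)) {
    tp <- sum(truth[, i] == 1 & pred[, i] == 1)
    fn <- sum(truth[, i] == 1 & pred[, i] == 0)
    fp <- sum(truth[, i] == 0 & pred[, i] == 1)
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
  }
  r <- mean(rec); p <- mean(prec)
  list(recall = r, precision = p,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

test_that("macro metrics match hand-computed confusion cases", {
  perfect <- tibble::tibble(type = c("a", "b"), tp = c(3, 2), fp = 0,
                            fn = 0, tn = c(2, 3))
  m <- macro_metrics(perfect)
  expect_equal(m$macro_recall, 1)
  expect_equal(m$macro_precision, 1)
  expect_equal(m$macro_f1, 1)
  # (TP,FP,FN) = (3,1,1) and (1,3,3): both macro means are 0.5
  two <- tibble::tibble(type = c("a", "b"), tp = c(3, 1), fp = c(1, 3),
                        fn = c(1, 3), tn = 0)
  m2 <- macro_metrics(two)
  expect_equal(m2$macro_recall, 0.5)
  expect_equal(m2$macro_precision, 0.5)
  expect_equal(m2$macro_f1, 0.5)
  expect_error(macro_metrics(two[0, ]), ".")
})

test_that("an empty type contributes zero and matches the brute-force recount", {
  truth <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1), c = c(0, 0, 0, 0))
  pred <- cbind(a = c(1, 0, 0, 0), b = c(0, 0, 1, 1), c = c(0, 0, 0, 0))
  m <- suppressMessages(macro_metrics(confusion_counts(truth, pred)))
  oracle <- brute_force_macro(truth, pred)
  expect_equal(m$macro_recall, oracle$recall)
  expect_equal(m$macro_precision, oracle$precision)
  expect_equal(m$macro_f1, oracle$f1)
})

test_that("macro metrics agree with the recount oracle on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    n_types <- sample(2:10, 1)
    n_pairs <- sample(5:40, 1)
    truth <- matrix(rbinom(n_pairs * n_types, 1, 0.3), n_pairs)
    pred <- matrix(rbinom(n_pairs * n_types, 1, 0.3), n_pairs)
    colnames(truth) <- colnames(pred) <- paste0("t", seq_len(n_types))
    m <- suppressMessages(macro_metrics(confusion_counts(truth, pred)))
    oracle <- brute_force_macro(truth, pred)
    expect_equal(m$macro_recall, oracle$recall, tolerance = 1e-9)
    expect_equal(m$macro_precision, oracle$precision, tolerance = 1e-9)
    expect_equal(m$macro_f1, oracle$f1, tolerance = 1e-9)
    # harmonic-mean consistency of the stored value
    pr <- m$macro_precision; rc <- m$macro_recall
    if (pr + rc > 0) {
      expect_equal(m$macro_f1, 2 * pr * rc / (pr + rc), tolerance = 1e-12)
    }
  }
})

test_that("fold partitions are balanced, disjoint, exhaustive, deterministic", {
  st <- tiny_study()
  f1 <- make_folds(st$pairs, 5, seed = 4)
  f2 <- make_folds(st$pairs, 5, seed = 4)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  sizes <- table(f1)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), nrow(st$pairs))
  # near-stratification: every type with >= 5 pairs appears in every fold
  for (tl in unique(st$pairs$type_label)) {
    expect_setequal(unique(f1[st$pairs$type_label == tl]), 1:5)
  }
})

test_that("a constant single-type predictor scores the closed-form macro recall", {
  # 4 balanced types, classifier always predicts type 1:
  # recall = (1 + 0 + 0 + 0) / 4
  truth_labels <- rep(paste0("t", 1:4), each = 10)
  vocab <- paste0("t", 1:4)
  truth <- gcanddi:::one_hot_labels(truth_labels, vocab)
  pred <- matrix(0, 40, 4, dimnames = list(NULL, vocab))
  pred[, 1] <- 1
  m <- suppressMessages(macro_metrics(confusion_counts(truth, pred)))
  expect_equal(m$macro_recall, 0.25)
  expect_equal(m$macro_precision, 0.25 * 0.25)  # 10/40 correct, one type
})

test_that("paired fold comparison behaves like a t-test", {
  expect_equal(compare_methods(c(0.9, 0.91, 0.92, 0.9, 0.91),
                               c(0.9, 0.91, 0.92, 0.9, 0.91)), 1)
  a <- c(0.95, 0.96, 0.94, 0.95, 0.96)
  b <- c(0.60, 0.61, 0.59, 0.60, 0.61)
  expect_lt(compare_methods(a, b), 0.01)
  # cross-check against the reference implementation
  x <- c(0.9, 0.91, 0.88, 0.93, 0.9)
  y <- c(0.89, 0.9, 0.89, 0.91, 0.9)
  expect_equal(compare_methods(x, y), t.test(x, y, paired = TRUE)$p.value)
  expect_error(compare_methods(1, c(1, 2)), "equal length")
  expect_error(compare_methods(1, 2), "at least 2")
})

test_that("fivefold cross-validation evaluates every pair exactly once", {
  cl <- clean_study()
  feats <- signature_features(cl$drugs)
  cv <- suppressWarnings(fivefold_cv(
    cl$pairs, feats, method = "dnn",
    config = tiny_dnn_config(epochs = 60),
    seed = 2, feature_kind = "original"
  ))
  tf <- tidy(cv)
  expect_equal(nrow(tf), 5)
  expect_true(all(tf$macro_f1 >= 0 & tf$macro_f1 <= 1))
  g <- glance(cv)
  expect_match(g$macro_f1, "% ± ")
  expect_equal(g$macro_f1_mean, mean(tf$macro_f1))
  # separable data should cross-validate near-perfectly
  expect_gt(g$macro_f1_mean, 0.9)
})

test_that("nearest-neighbour consistency handles identity and tie cases", {
  feats <- tibble::tibble(
    drug_id = c("a1", "a2", "a3", "b1", "b2"),
    f1 = c(0, 0.1, 0.2, 10, 10.1),
    f2 = c(0, 0.1, 0.2, 10, 10.1)
  )
  groups <- list(concordant = c("a1", "a2", "a3"), other = c("b1", "b2"))
  # tight cluster, self-matches excluded: everyone's neighbour is in-group
  expect_equal(neighbor_consistency(c("a1", "a2", "a3"), groups, feats), 1)
  expect_equal(neighbor_consistency(c("b1", "b2"), groups, feats,
                                    concordant = "other"), 1)
  expect_error(neighbor_consistency("a1", list(), feats), "non-empty")
  expect_error(neighbor_consistency("a1", list(g = "a2", h = "a2"), feats),
               "disjoint")
  # exact ties resolved by ascending drug id, matching a brute-force scan
  tied <- tibble::tibble(drug_id = c("q", "m1", "m2"), f1 = c(0, 1, 1))
  expect_equal(
    neighbor_consistency("q", list(g1 = "m1", g2 = "m2"), tied,
                         concordant = "g1"),
    1
  )
})

test_that("random features give chance-level neighbour consistency", {
  set.seed(77)
  fracs <- replicate(30, {
    feats <- tibble::tibble(
      drug_id = sprintf("d%02d", 1:20),
      f1 = rnorm(20), f2 = rnorm(20)
    )
    groups <- list(g1 = feats$drug_id[1:10], g2 = feats$drug_id[11:20])
    neighbor_consistency(feats$drug_id[1:10], groups, feats)
  })
  # balanced groups: expected fraction ~ (group share of remaining drugs)
  expect_gt(mean(fracs), 0.25)
  expect_lt(mean(fracs), 0.75)
})

test_that("the feature-by-method grid produces the full comparison table", {
  cl <- clean_study()
  feats_orig <- signature_features(cl$drugs)
  m <- train_gcan(cl$drugs, cl$graph, tiny_gcan_config(epochs = 60))
  feats_gcan <- embed_drugs(m, cl$drugs)
  grid <- suppressWarnings(run_feature_model_grid(
    cl$pairs,
    list(original = feats_orig, gcan = feats_gcan),
    methods = c("dnn", "lstm"),
    configs = list(dnn = tiny_dnn_config(epochs = 40),
                   lstm = tiny_lstm_config(epochs = 40)),
    seed = 3
  ))
  expect_equal(nrow(grid$table), 4)  # 2 features x 2 methods
  expect_setequal(grid$table$feature_kind, c("original", "gcan"))
  ref_rows <- grid$table$feature_kind == "gcan"
  expect_true(all(is.na(grid$table$p_value_vs_ref[ref_rows])))
  expect_true(all(!is.na(grid$table$p_value_vs_ref[!ref_rows])))
})
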
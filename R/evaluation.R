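# Macro-averaged multi-label evaluation, fivefold cross-validation over
# DDI pairs, fold-level paired significance testing, and the
# nearest-training-neighbour consistency diagnostic.

#' Per-type confusion counts for multi-label predictions
#'
#' @param truth n_pairs x n_types 0/1 matrix (columns named by type), or a
#'   character vector of single true labels plus `vocab`.
#' @param pred n_pairs x n_types 0/1 matrix of decoded predictions.
#' @param vocab Label vocabulary (needed when `truth` is a vector).
#' @return A tibble with one row per type: `type`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(truth, pred, vocab = NULL) {
  if (!is.matrix(truth)) {
    vocab <- vocab %||% sort(unique(as.character(truth)))
    truth <- one_hot_labels(as.character(truth), vocab)
  }
  vocab <- colnames(truth)
  stopifnot(is.matrix(pred), ncol(pred) == ncol(truth),
            nrow(pred) == nrow(truth))
  tp <- colSums(pred == 1 & truth == 1)
  fp <- colSums(pred == 1 & truth == 0)
  fn <- colSums(pred == 0 & truth == 1)
  tn <- colSums(pred == 0 & truth == 0)
  tibble(type = vocab, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Macro-averaged recall, precision and F1
#'
#' Macro-recall is the unweighted mean over types of `TP / (TP + FN)`,
#' macro-precision the mean of `TP / (TP + FP)`, and macro-F1 the harmonic
#' mean `2PR / (P + R)` of those two macro averages. A type whose
#' denominator is zero contributes 0 to the mean (the conventional
#' library behaviour; a message notes it).
#'
#' @param counts Confusion-count tibble from [confusion_counts()].
#' @param fold_id Optional identifier recorded on the result.
#' @return An object of class `macro_metrics`: list with `macro_recall`,
#'   `macro_precision`, `macro_f1`, the per-type breakdown and `fold_id`.
#' @export
macro_metrics <- function(counts, fold_id = NA) {
  stopifnot(is.data.frame(counts), nrow(counts) >= 1,
            all(c("type", "tp", "fp", "fn") %in% names(counts)))
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, 0)
  rec <- safe_ratio(counts$tp, counts$tp + counts$fn)
  prec <- safe_ratio(counts$tp, counts$tp + counts$fp)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  if (any(counts$tp + counts$fn == 0) || any(counts$tp + counts$fp == 0)) {
    inform("Zero-denominator type(s) scored 0 in the macro average.")
  }
  macro_r <- mean(rec)
  macro_p <- mean(prec)
  macro_f1 <- if (macro_p + macro_r > 0) {
    2 * macro_p * macro_r / (macro_p + macro_r)
  } else {
    0
  }
  structure(
    list(
      macro_recall = macro_r, macro_precision = macro_p, macro_f1 = macro_f1,
      per_type = tibble(type = counts$type, recall = rec, precision = prec,
                        f1 = f1),
      fold_id = fold_id
    ),
    class = "macro_metrics"
  )
}

#' @export
print.macro_metrics <- function(x, ...) {
  cat(sprintf(
    "<macro_metrics> F1 %.3f | recall %.3f | precision %.3f (%d types)\n",
    x$macro_f1, x$macro_recall, x$macro_precision, nrow(x$per_type)
  ))
  invisible(x)
}

#' Per-type breakdown of macro metrics
#'
#' @param x A `macro_metrics` object.
#' @param ... Unused.
#' @return Tibble with `type`, `recall`, `precision`, `f1`.
#' @method tidy macro_metrics
#' @export
tidy.macro_metrics <- function(x, ...) x$per_type

#' One-row macro summary
#'
#' @param x A `macro_metrics` object.
#' @param ... Unused.
#' @return One-row tibble of the three macro averages.
#' @method glance macro_metrics
#' @export
glance.macro_metrics <- function(x, ...) {
  tibble(
    fold_id = x$fold_id,
    macro_f1 = x$macro_f1,
    macro_recall = x$macro_recall,
    macro_precision = x$macro_precision
  )
}

# Macro metrics straight from a prediction tibble (predict.ddi_classifier
# output carrying the true type_label).
metrics_from_predictions <- function(pred, vocab, fold_id = NA) {
  truth <- one_hot_labels(as.character(pred$type_label), vocab)
  P <- prediction_matrix(pred, vocab)
  macro_metrics(confusion_counts(truth, P), fold_id = fold_id)
}

#' Partition DDI pairs into cross-validation folds
#'
#' Pairs are shuffled within type and dealt round-robin across the
#' type-blocked ordering, so folds are balanced in size (differing by at
#' most one) and every type is spread across folds as evenly as its count
#' allows.
#'
#' @param pairs Tibble of DDI pairs with `type_label`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments (1..n_folds), one per row.
#' @export
make_folds <- function(pairs, n_folds = 5, seed = 1L) {
  n_folds <- check_count(n_folds, "n_folds")
  with_seed(derive_seed(seed, "folds"), {
    ord <- order(pairs$type_label, runif(nrow(pairs)))
    fold <- integer(nrow(pairs))
    fold[ord] <- rep_len(seq_len(n_folds), nrow(pairs))
    fold
  })
}

#' Fivefold cross-validation of a DDI classifier
#'
#' Partitions pairs once (stratified by type), trains on four fifths and
#' evaluates macro metrics on the held-out fifth, five times. If a fold's
#' training part lacks a type entirely a warning is logged and the type is
#' still scored on the test side.
#'
#' @param pairs Tibble of `drug_a`, `drug_b`, `type_label`.
#' @param features Feature tibble (`drug_id` + numeric columns).
#' @param method `"lstm"` or `"dnn"`.
#' @param config An [lstm_config()] or [dnn_config()] matching `method`.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the partition (training seeds derive from it).
#' @param feature_kind Tag recorded on results.
#' @return An object of class `ddi_cv`: per-fold `macro_metrics`, the fold
#'   assignment, and mean/sd summaries.
#' @export
fivefold_cv <- function(pairs, features, method = c("lstm", "dnn"),
                        config = NULL, n_folds = 5, seed = 1L,
                        feature_kind = "unknown") {
  method <- match.arg(method)
  config <- config %||% if (method == "lstm") lstm_config() else dnn_config()
  vocab <- sort(unique(as.character(pairs$type_label)))
  fold <- make_folds(pairs, n_folds, seed)
  folds <- sort(unique(fold))
  per_fold <- lapply(folds, function(k) {
    train <- pairs[fold != k, , drop = FALSE]
    test <- pairs[fold == k, , drop = FALSE]
    absent <- setdiff(vocab, unique(train$type_label))
    if (length(absent) > 0) {
      warn(sprintf("Fold %d: type(s) absent from training data: %s",
                   k, paste(absent, collapse = ", ")))
    }
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("fold", k, "-", config$seed))
    fit <- if (method == "lstm") {
      train_lstm(train, features, cfg, feature_kind)
    } else {
      train_dnn_baseline(train, features, cfg, feature_kind)
    }
    pred <- predict(fit, features, test)
    metrics_from_predictions(pred, vocab, fold_id = k)
  })
  structure(
    list(
      per_fold = per_fold, fold = fold, method = method,
      feature_kind = feature_kind, vocab = vocab, seed = seed
    ),
    class = "ddi_cv"
  )
}

format_pct_pm <- function(m, s) sprintf("%.1f%% ± %.1f%%", 100 * m, 100 * s)

#' Per-fold metrics of a cross-validation run
#'
#' @param x A `ddi_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @method tidy ddi_cv
#' @export
tidy.ddi_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(x$per_fold, glance)) |>
    mutate(method = x$method, feature_kind = x$feature_kind, .before = 1)
}

#' Mean and sd summary of a cross-validation run
#'
#' @param x A `ddi_cv` object.
#' @param ... Unused.
#' @return One-row tibble with per-metric mean, sample sd (n - 1), and
#'   `"xx.x% ± x.x%"` display strings.
#' @method glance ddi_cv
#' @export
glance.ddi_cv <- function(x, ...) {
  tf <- tidy(x)
  tibble(
    method = x$method,
    feature_kind = x$feature_kind,
    n_folds = nrow(tf),
    macro_f1_mean = mean(tf$macro_f1), macro_f1_sd = sd(tf$macro_f1),
    macro_recall_mean = mean(tf$macro_recall),
    macro_recall_sd = sd(tf$macro_recall),
    macro_precision_mean = mean(tf$macro_precision),
    macro_precision_sd = sd(tf$macro_precision),
    macro_f1 = format_pct_pm(mean(tf$macro_f1), sd(tf$macro_f1)),
    macro_recall = format_pct_pm(mean(tf$macro_recall), sd(tf$macro_recall)),
    macro_precision = format_pct_pm(mean(tf$macro_precision),
                                    sd(tf$macro_precision))
  )
}

#' @export
print.ddi_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ddi_cv> %s on %s features (%d folds): F1 %s, recall %s, precision %s\n",
    toupper(x$method), x$feature_kind, g$n_folds,
    g$macro_f1, g$macro_recall, g$macro_precision
  ))
  invisible(x)
}

#' Compare two cross-validated methods on paired folds
#'
#' Paired two-sided t-test over per-fold values of one metric, for two
#' models evaluated on the same fold partition. Identical fold vectors
#' (all differences zero) return p = 1.
#'
#' @param metrics_a,metrics_b `ddi_cv` objects (or numeric per-fold
#'   vectors of equal length).
#' @param metric Which metric to compare when `ddi_cv` objects are given.
#' @return The two-sided p-value.
#' @export
compare_methods <- function(metrics_a, metrics_b, metric = "macro_f1") {
  pull_vec <- function(m) {
    if (inherits(m, "ddi_cv")) tidy(m)[[metric]] else as.numeric(m)
  }
  a <- pull_vec(metrics_a)
  b <- pull_vec(metrics_b)
  if (length(a) != length(b)) {
    abort("Fold vectors must have equal length (same partition).")
  }
  if (length(a) < 2) {
    abort("Need at least 2 folds to test a difference.")
  }
  d <- a - b
  if (sd(d) == 0) {
    return(if (all(d == 0)) 1 else 0)
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Nearest-training-neighbour consistency of predicted drugs
#'
#' For each drug in `predicted_drugs`, finds its single most similar drug
#' (inverse-squared-distance similarity over the supplied feature space)
#' among the union of the reference groups, excluding itself, and returns
#' the fraction of predicted drugs whose nearest neighbour belongs to the
#' concordant group. Ties in similarity break in ascending drug-id order.
#'
#' @param predicted_drugs Character vector of drug ids.
#' @param reference_groups Named list of disjoint character vectors of drug
#'   ids (the known interaction groups in the training set).
#' @param features Feature tibble covering all drugs involved.
#' @param concordant Name of the group counted as concordant (default the
#'   first group).
#' @return Fraction in `[0, 1]`.
#' @export
neighbor_consistency <- function(predicted_drugs, reference_groups, features,
                                 concordant = names(reference_groups)[1]) {
  if (length(reference_groups) == 0 ||
      any(lengths(reference_groups) == 0)) {
    abort("`reference_groups` must be non-empty groups of drug ids.")
  }
  if (is.null(names(reference_groups))) {
    abort("`reference_groups` must be named.")
  }
  if (anyDuplicated(unlist(reference_groups)) > 0) {
    abort("`reference_groups` must be disjoint.")
  }
  fm <- feature_matrix(features)
  ref_ids <- unlist(reference_groups, use.names = FALSE)
  missing <- setdiff(c(predicted_drugs, ref_ids), rownames(fm))
  if (length(missing) > 0) {
    abort(sprintf("Drug id(s) not in the feature table: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  ref_ids <- ref_ids[order(ref_ids)]  # id order fixes tie-breaks
  group_of <- setNames(
    rep(names(reference_groups), lengths(reference_groups)),
    unlist(reference_groups, use.names = FALSE)
  )
  hits <- vapply(predicted_drugs, function(id) {
    cand <- setdiff(ref_ids, id)
    if (length(cand) == 0) return(NA)
    d2 <- colSums((t(fm[cand, , drop = FALSE]) - fm[id, ])^2)
    sims <- 1 / (d2 + 1)
    nn <- cand[which.max(sims)]
    group_of[[nn]] == concordant
  }, logical(1))
  mean(hits, na.rm = TRUE)
}

#' Run the feature-by-method comparison grid
#'
#' Cross-validates every combination of feature space and classifier on one
#' pair list and one fold partition — the standard comparison-table layout
#' (rows: feature space, method; columns: macro metrics, with a paired
#' p-value against the reference feature space within each method).
#'
#' @param pairs Tibble of DDI pairs.
#' @param feature_sets Named list of feature tibbles, e.g.
#'   `list(original = ..., autoencoder = ..., gcan = ...)`.
#' @param methods Character vector out of `"dnn"`, `"lstm"`.
#' @param configs Named list of configs per method (defaults used if NULL).
#' @param n_folds,seed Cross-validation partition settings.
#' @param reference_feature Feature space that p-values compare against
#'   (default `"gcan"` if present, else the last feature set).
#' @return A list with `table` (one summary row per grid cell, including
#'   formatted `"xx.x% ± x.x%"` strings and `p_value_vs_ref`) and `runs`
#'   (the underlying `ddi_cv` objects, named `feature.method`).
#' @export
run_feature_model_grid <- function(pairs, feature_sets,
                                   methods = c("dnn", "lstm"),
                                   configs = NULL, n_folds = 5, seed = 1L,
                                   reference_feature = NULL) {
  stopifnot(is.list(feature_sets), !is.null(names(feature_sets)))
  methods <- match.arg(methods, c("dnn", "lstm"), several.ok = TRUE)
  reference_feature <- reference_feature %||%
    if ("gcan" %in% names(feature_sets)) "gcan" else utils::tail(names(feature_sets), 1)
  runs <- list()
  for (m in methods) {
    cfg <- configs[[m]] %||% if (m == "lstm") lstm_config() else dnn_config()
    for (f in names(feature_sets)) {
      runs[[paste(f, m, sep = ".")]] <- fivefold_cv(
        pairs, feature_sets[[f]], method = m, config = cfg,
        n_folds = n_folds, seed = seed, feature_kind = f
      )
    }
  }
  table <- dplyr::bind_rows(lapply(runs, glance))
  table$p_value_vs_ref <- vapply(runs, function(r) {
    if (r$feature_kind == reference_feature) return(NA_real_)
    ref <- runs[[paste(reference_feature, r$method, sep = ".")]]
    compare_methods(r, ref)
  }, numeric(1))
  list(table = table, runs = runs)
}

#' Plot per-fold macro metrics across grid cells
#'
#' @param object A `ddi_cv` object, or the result of
#'   [run_feature_model_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ddi_cv
#' @export
autoplot.ddi_cv <- function(object, ...) {
  tf <- tidy(object) |>
    tidyr::pivot_longer(c("macro_f1", "macro_recall", "macro_precision"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(tf, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "#a6bddb") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s on %s features", toupper(object$method),
                      object$feature_kind),
      x = NULL, y = "Per-fold value"
    ) +
    ggplot2::theme_minimal()
}

#' Compare grid cells graphically
#'
#' @param grid Result of [run_feature_model_grid()].
#' @return A ggplot of per-fold macro-F1 by feature space and method.
#' @export
plot_grid_results <- function(grid) {
  tf <- dplyr::bind_rows(lapply(grid$runs, tidy))
  ggplot2::ggplot(
    tf,
    ggplot2::aes(x = .data$feature_kind, y = .data$macro_f1,
                 fill = .data$method)
  ) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "Feature space", y = "Per-fold macro-F1", fill = "Model") +
    ggplot2::theme_minimal()
}
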
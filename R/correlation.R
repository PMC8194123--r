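# Similarity-profile correlation diagnostics: how well does a feature
# space's drug-drug similarity structure agree with chemical-structure
# similarity? Each drug is represented by its profile of similarities to
# every other drug, and profiles from two feature spaces are compared with
# a per-drug Pearson correlation.

#' Inverse-squared-distance similarity between two feature vectors
#'
#' `1 / (sum_i (x_i - y_i)^2 + 1)`: 1 for identical vectors, decreasing
#' monotonically in squared Euclidean distance, always positive.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Similarity in `(0, 1]`.
#' @export
euclidean_similarity <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("Dimension mismatch: %d vs %d.", length(x), length(y)))
  }
  1 / (sum((x - y)^2) + 1)
}

#' Pairwise drug-similarity matrix under a chosen similarity
#'
#' @param features For `kind = "euclidean"`, a feature tibble (`drug_id` +
#'   numeric columns) or numeric matrix with drug-id rownames. For
#'   `kind = "tanimoto"`, a drug table with `fp*` columns or a 0/1 matrix.
#' @param kind `"euclidean"` (inverse squared distance, for real-valued
#'   signatures and embeddings) or `"tanimoto"` (for fingerprints).
#' @return Symmetric n x n matrix with unit diagonal and drug ids as
#'   dimnames.
#' @export
similarity_matrix <- function(features, kind = c("euclidean", "tanimoto")) {
  kind <- match.arg(kind)
  if (kind == "tanimoto") {
    fp <- if (is.matrix(features)) features else fp_matrix(features)
    if (nrow(fp) < 2) abort("Need at least two drugs.")
    return(tanimoto_matrix(fp))
  }
  m <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(m) < 2) abort("Need at least two drugs.")
  sq <- rowSums(m^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(m)
  d2[d2 < 0] <- 0  # numerical guard
  s <- 1 / (d2 + 1)
  diag(s) <- 1
  dimnames(s) <- list(rownames(m), rownames(m))
  s
}

#' Per-drug Pearson correlation between two similarity profiles
#'
#' Represents each drug by its row of similarities to all drugs under two
#' feature spaces and correlates the two rows. Self-similarity entries
#' (identically 1 in both spaces) are excluded from each profile before
#' computing r, so the shared constant point cannot inflate the
#' correlation. A zero-variance profile yields `NA` for that drug and is
#' excluded from the median.
#'
#' @param profiles_a,profiles_b n x n similarity matrices over the same
#'   drugs in the same order (from [similarity_matrix()]).
#' @param exclude_self Drop the diagonal entry from each profile
#'   (default `TRUE`).
#' @return An object of class `profile_correlation`: tibble of per-drug
#'   `r` plus attributes; use [glance()] for the median summary.
#' @export
profile_correlation <- function(profiles_a, profiles_b, exclude_self = TRUE) {
  stopifnot(is.matrix(profiles_a), is.matrix(profiles_b))
  if (!all(dim(profiles_a) == dim(profiles_b))) {
    abort("Profile matrices must have identical dimensions.")
  }
  if (!is.null(rownames(profiles_a)) && !is.null(rownames(profiles_b)) &&
      !identical(rownames(profiles_a), rownames(profiles_b))) {
    abort("Profile matrices must cover the same drugs in the same order.")
  }
  n <- nrow(profiles_a)
  ids <- rownames(profiles_a) %||% as.character(seq_len(n))
  r <- vapply(seq_len(n), function(i) {
    x <- profiles_a[i, ]
    y <- profiles_b[i, ]
    if (exclude_self) {
      x <- x[-i]
      y <- y[-i]
    }
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  structure(
    tibble(drug_id = ids, r = r),
    class = c("profile_correlation", class(tibble())),
    median_r = stats::median(r, na.rm = TRUE)
  )
}

#' Median of a per-drug profile-correlation distribution
#'
#' @param x A `profile_correlation` object.
#' @param ... Unused.
#' @return One-row tibble: `n_drugs`, `n_defined` (non-missing r), and
#'   `median_r`.
#' @method glance profile_correlation
#' @export
glance.profile_correlation <- function(x, ...) {
  tibble(
    n_drugs = nrow(x),
    n_defined = sum(!is.na(x$r)),
    median_r = attr(x, "median_r")
  )
}

#' Correlation between feature spaces and structure, per feature set
#'
#' Convenience wrapper for the standard diagnostic: computes the Tanimoto
#' structure-similarity matrix once and correlates each supplied feature
#' space's similarity profiles against it.
#'
#' @param drugs Drug table with `fp*` fingerprint columns.
#' @param feature_sets Named list of feature tibbles (e.g. raw signatures,
#'   autoencoder embedding, GCAN embedding).
#' @return Tibble: `feature_kind`, `drug_id`, `r` for every drug and set.
#' @export
structure_correlation_table <- function(drugs, feature_sets) {
  stopifnot(is.list(feature_sets), !is.null(names(feature_sets)))
  s_structure <- similarity_matrix(drugs, "tanimoto")
  purrr::imap(feature_sets, function(f, name) {
    s <- similarity_matrix(f, "euclidean")
    pc <- profile_correlation(s, s_structure)
    tibble(feature_kind = name, drug_id = pc$drug_id, r = pc$r)
  }) |>
    dplyr::bind_rows()
}

#' Plot per-drug structure-correlation distributions
#'
#' @param corr_table Output of [structure_correlation_table()].
#' @return A ggplot density plot of per-drug r by feature space.
#' @export
plot_correlation_distribution <- function(corr_table) {
  ggplot2::ggplot(
    corr_table,
    ggplot2::aes(x = .data$r, colour = .data$feature_kind,
                 fill = .data$feature_kind)
  ) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::labs(
      x = "Per-drug Pearson r (feature profile vs structure profile)",
      y = "Density", colour = "Features", fill = "Features"
    ) +
    ggplot2::theme_minimal()
}

#' Similarity heat map of a drug subset
#'
#' @param features Feature tibble or drug table (see [similarity_matrix()]).
#' @param kind Similarity kind.
#' @param drug_ids Optional subset of drugs to display.
#' @return A ggplot tile heat map.
#' @export
plot_similarity_heatmap <- function(features, kind = "euclidean",
                                    drug_ids = NULL) {
  s <- similarity_matrix(features, kind)
  if (!is.null(drug_ids)) s <- s[drug_ids, drug_ids, drop = FALSE]
  df <- as_tibble(as.table(s), .name_repair = ~ c("drug_a", "drug_b", "sim"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug_a, y = .data$drug_b,
                                   fill = .data$sim)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
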
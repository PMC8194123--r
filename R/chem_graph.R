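# Chemical-structure side of the model: Morgan fingerprints, Tanimoto
# similarity, and the top-k row-normalized drug-similarity graph that the
# graph convolutional autoencoder propagates over.

#' Morgan (ECFP) fingerprint of a SMILES string
#'
#' Computes a hashed circular fingerprint via OpenBabel (through the
#' ChemmineOB package). OpenBabel's ECFP implementation hashes to a fixed
#' 4096-bit vector; fingerprints are folded down to `n_bits` by OR-ing bits
#' that share an index modulo `n_bits`, the standard fingerprint-folding
#' construction. `radius` follows the ECFP naming convention: radius 2 is
#' ECFP4.
#'
#' @param smiles A single SMILES string.
#' @param radius Circular neighbourhood radius (default 2, ECFP4).
#' @param n_bits Folded fingerprint length (default 1024; must not exceed
#'   4096).
#' @return Integer vector of 0/1 bits, length `n_bits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 1024) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    abort("`smiles` must be a single SMILES string.")
  }
  radius <- check_count(radius, "radius", min = 0L)
  n_bits <- check_count(n_bits, "n_bits")
  if (n_bits > 4096L) {
    abort("`n_bits` must not exceed 4096 (the native ECFP width).")
  }
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("Package `ChemmineOB` is required for SMILES fingerprinting.")
  }
  fp_name <- paste0("ECFP", 2L * radius)
  raw <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
      ChemmineOB::fingerprint_OB(list(mol), fp_name)
    })[[1]],
    error = function(e) {
      abort(sprintf("Cannot parse SMILES '%s': %s", smiles, conditionMessage(e)))
    }
  )
  folded <- integer(n_bits)
  on_bits <- which(raw > 0)
  folded[unique((on_bits - 1L) %% n_bits + 1L)] <- 1L
  folded
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' `|a AND b| / |a OR b|`. Two all-zero fingerprints are defined to have
#' similarity 1 (the 0/0 case; a warning is emitted once per call).
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("Fingerprint lengths differ (%d vs %d).", length(a), length(b)))
  }
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) {
    warn("Tanimoto of two all-zero fingerprints; returning 1 by convention.")
    return(1)
  }
  inter / uni
}

# All pairwise Tanimoto similarities of the rows of a 0/1 matrix, via bit
# counting: |a AND b| = a . b, |a OR b| = |a| + |b| - |a AND b|.
tanimoto_matrix <- function(fp) {
  fp <- as.matrix(fp)
  storage.mode(fp) <- "double"
  inter <- tcrossprod(fp)
  ones <- rowSums(fp)
  uni <- outer(ones, ones, "+") - inter
  s <- inter / uni
  s[uni == 0] <- 1  # all-zero vs all-zero convention
  dimnames(s) <- list(rownames(fp), rownames(fp))
  s
}

# Fingerprint / signature column accessors for wide drug tables.
fp_matrix <- function(drugs) {
  cols <- grep("^fp[0-9]+$", names(drugs), value = TRUE)
  if (length(cols) == 0) abort("No fingerprint columns (fp1, fp2, ...) found.")
  m <- as.matrix(drugs[cols])
  rownames(m) <- drugs$drug_id
  m
}

signature_matrix <- function(drugs) {
  cols <- grep("^g[0-9]+$", names(drugs), value = TRUE)
  if (length(cols) == 0) abort("No signature columns (g1, g2, ...) found.")
  m <- as.matrix(drugs[cols])
  rownames(m) <- drugs$drug_id
  m
}

#' Build the top-k row-normalized drug-similarity graph
#'
#' Each drug is connected to (at most) the `k` drugs with the most similar
#' chemical structure under the Tanimoto coefficient: per row of the
#' pairwise similarity matrix the `k` largest off-diagonal values are
#' retained and the rest set to 0. A self-weight of 1 (the maximum possible
#' similarity) is placed on the diagonal before normalization so that a
#' node's own features participate in the graph convolution; then every row
#' is divided by its sum, giving a row-stochastic edge-weight matrix. Ties
#' at the k-th rank break in drug-id order. A row whose similarities to all
#' other drugs are 0 degenerates to a self-loop-only row. Row-wise top-k
#' selection is not symmetric and no symmetrization is applied.
#'
#' @param drugs A drug table carrying `fp*` fingerprint columns, or a plain
#'   0/1 matrix with drug ids as rownames.
#' @param k Maximum retained neighbours per row (default 40).
#' @param self_loop Include the unit self-weight (default `TRUE`).
#' @return An object of class `similarity_graph`: list with `drug_ids` and
#'   the n x n row-stochastic `weights` matrix.
#' @export
build_similarity_graph <- function(drugs, k = 40, self_loop = TRUE) {
  k <- check_count(k, "k")
  fp <- if (is.matrix(drugs)) drugs else fp_matrix(drugs)
  if (nrow(fp) < 1) abort("Need at least one drug.")
  s <- tanimoto_matrix(fp)
  n <- nrow(s)
  w <- matrix(0, n, n, dimnames = dimnames(s))
  for (i in seq_len(n)) {
    sims <- s[i, ]
    sims[i] <- -Inf  # self handled separately
    keep_n <- min(k, n - 1L)
    if (keep_n > 0) {
      # ties at the k-th rank break by ascending drug-id position
      ord <- order(sims, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
      top <- ord[seq_len(keep_n)]
      top <- top[sims[top] > 0]
      w[i, top] <- sims[top]
    }
  }
  if (self_loop) {
    diag(w) <- 1
  } else {
    empty <- rowSums(w) == 0
    if (any(empty)) {
      # keep the matrix row-stochastic even without self-loops
      diag(w)[empty] <- 1
    }
  }
  w <- w / rowSums(w)
  structure(
    list(drug_ids = rownames(fp), weights = w),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  nnz <- sum(x$weights > 0) - sum(diag(x$weights) > 0)
  cat(sprintf(
    "<similarity_graph> %d drugs, %d directed edges (row-stochastic)\n",
    length(x$drug_ids), nnz
  ))
  invisible(x)
}

#' Tidy a similarity graph into an edge list
#'
#' @param x A `similarity_graph`.
#' @param ... Unused.
#' @return A tibble with `source_id`, `target_id`, `weight` rows for every
#'   nonzero edge (self-loops included).
#' @method tidy similarity_graph
#' @export
tidy.similarity_graph <- function(x, ...) {
  idx <- which(x$weights > 0, arr.ind = TRUE)
  tibble(
    source_id = x$drug_ids[idx[, 1]],
    target_id = x$drug_ids[idx[, 2]],
    weight = x$weights[idx]
  ) |>
    arrange(.data$source_id, .data$target_id)
}
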
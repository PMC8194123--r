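# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n count across all_of row_number
#' @importFrom purrr map map_dbl map2 pmap imap
#' @importFrom stats rnorm runif setNames cor sd t.test
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points route their randomness through this so that a
# given seed yields byte-identical output regardless of ambient RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream label, staying inside
# 32-bit integer range. Streams keep independent stages (drug simulation,
# weight init, batch shuffling, ...) decoupled under one user-facing seed.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d (got %s).",
                  name, min, deparse(x)))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name))
  }
  as.numeric(x)
}

# Extract the n x d numeric matrix (rownames = drug ids) from a feature
# tibble whose first column is `drug_id` and remaining columns are numeric.
feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "drug_id" %in% names(features))
  m <- as.matrix(features[setdiff(names(features), "drug_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(features$drug_id)
  m
}

matrix_to_feature_tbl <- function(m, prefix = "e") {
  colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(drug_id = rownames(m)), out)
  out
}
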
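#' Configuration for the synthetic drug / DDI generator
#'
#' Bundles every knob of the synthetic benchmark into a validated list. The
#' generator plants a latent class structure: each structural class owns a
#' prototype fingerprint; a drug's fingerprint is its class prototype with
#' independent per-bit flips, and its transcriptome signature is a fixed
#' random linear image of that fingerprint plus Gaussian noise. Typed DDIs
#' are then a deterministic function of the two drugs' latent classes, so
#' every downstream stage (graph, embedding, classification, evaluation) has
#' a recoverable ground truth.
#'
#' @param n_drugs Number of drugs to simulate.
#' @param n_classes Number of latent structural classes (`<= n_drugs`).
#' @param fp_bits Fingerprint length in bits (default 1024, matching the
#'   decoder output width of [gcan_config()]).
#' @param sig_dim Transcriptome signature length (default 977, the number of
#'   landmark genes in an L1000-style profile).
#' @param bit_flip_rate Probability that any fingerprint bit is flipped away
#'   from its class prototype.
#' @param expr_noise_sd Standard deviation of the additive Gaussian noise on
#'   signatures. At 0 (and `bit_flip_rate = 0`) drugs of one class have
#'   identical signatures.
#' @param n_types Number of DDI types to plant (must not exceed
#'   `n_classes^2`, the number of ordered class combinations).
#' @param pairs_per_type_min Minimum surviving pairs per type; types falling
#'   below this after generation are dropped, mirroring the gold-standard
#'   filter that discards interaction types with fewer than 5 pairs.
#' @param n_pairs Number of ordered drug pairs to sample (without
#'   replacement) before the per-type floor is applied. Default scales with
#'   `n_types`.
#' @param seed Integer seed; identical configs yield byte-identical tables.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_drugs()], [simulate_ddis()]
#' @export
simulation_config <- function(n_drugs,
                              n_classes,
                              fp_bits = 1024,
                              sig_dim = 977,
                              bit_flip_rate = 0.1,
                              expr_noise_sd = 2,
                              n_types = 4,
                              pairs_per_type_min = 5,
                              n_pairs = 60L * n_types,
                              seed = 1L) {
  n_drugs <- check_count(n_drugs, "n_drugs")
  n_classes <- check_count(n_classes, "n_classes")
  if (n_classes > n_drugs) {
    abort("`n_classes` must not exceed `n_drugs`.")
  }
  fp_bits <- check_count(fp_bits, "fp_bits")
  sig_dim <- check_count(sig_dim, "sig_dim")
  bit_flip_rate <- check_prob(bit_flip_rate, "bit_flip_rate")
  expr_noise_sd <- check_nonneg(expr_noise_sd, "expr_noise_sd")
  n_types <- check_count(n_types, "n_types")
  if (n_types > 80L) {
    abort("`n_types` must be at most 80.")
  }
  pairs_per_type_min <- check_count(pairs_per_type_min, "pairs_per_type_min", min = 5L)
  n_pairs <- check_count(n_pairs, "n_pairs")
  structure(
    list(
      n_drugs = n_drugs, n_classes = n_classes, fp_bits = fp_bits,
      sig_dim = sig_dim, bit_flip_rate = bit_flip_rate,
      expr_noise_sd = expr_noise_sd, n_types = n_types,
      pairs_per_type_min = pairs_per_type_min, n_pairs = n_pairs,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a drug table with planted structural classes
#'
#' Draws one prototype fingerprint per latent class (independent fair bits),
#' assigns drugs to classes round-robin, flips each drug's prototype bits
#' independently at `bit_flip_rate`, and maps the resulting fingerprint
#' through a fixed seeded linear map (entries `N(0, 1/fp_bits)`) to produce
#' the signature, to which `N(0, expr_noise_sd^2)` noise is added. The
#' SMILES column carries the placeholder token `"*"`: fingerprints are
#' sampled directly, so no chemistry toolkit is involved.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per drug: `drug_id`, `smiles`, `class`
#'   (latent ground-truth class), fingerprint bit columns `fp1..fpB` and
#'   signature columns `g1..gD`.
#' @export
simulate_drugs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "drugs"), {
    n <- config$n_drugs
    b <- config$fp_bits
    d <- config$sig_dim
    proto <- matrix(
      as.integer(runif(config$n_classes * b) < 0.5),
      nrow = config$n_classes
    )
    cls <- rep_len(seq_len(config$n_classes), n)
    fp <- proto[cls, , drop = FALSE]
    flips <- matrix(runif(n * b) < config$bit_flip_rate, nrow = n)
    fp[flips] <- 1L - fp[flips]
    # fixed linear map fingerprint -> signature, then additive noise
    map <- matrix(rnorm(b * d, sd = 1 / sqrt(b)), nrow = b)
    sig <- fp %*% map
    if (config$expr_noise_sd > 0) {
      sig <- sig + matrix(rnorm(n * d, sd = config$expr_noise_sd), nrow = n)
    }
    ids <- sprintf("D%04d", seq_len(n))
    colnames(fp) <- paste0("fp", seq_len(b))
    colnames(sig) <- paste0("g", seq_len(d))
    dplyr::bind_cols(
      tibble(drug_id = ids, smiles = "*", class = cls),
      as_tibble(fp),
      as_tibble(sig)
    )
  })
}

# Deterministic DDI type of an ordered class pair: ordered combinations
# (class_a, class_b) are laid out row-major and folded onto n_types.
planted_type <- function(class_a, class_b, n_classes, n_types) {
  idx <- (class_a - 1L) * n_classes + (class_b - 1L)
  sprintf("T%02d", (idx %% n_types) + 1L)
}

#' Simulate a typed DDI list over a simulated drug table
#'
#' Samples `n_pairs` ordered drug pairs uniformly without replacement
#' (`(a, b)` and `(b, a)` are distinct records; self-pairs are excluded),
#' labels each with a type that is a deterministic function of the two
#' drugs' latent classes, and then drops any type with fewer than
#' `pairs_per_type_min` pairs — the same floor the gold-standard
#' preparation applies to real interaction lists.
#'
#' @param drugs A drug table from [simulate_drugs()] (must carry the latent
#'   `class` column).
#' @param config The same [simulation_config()] used to create `drugs`.
#' @return A tibble of ordered pairs: `drug_a`, `drug_b`, `type_label`.
#' @export
simulate_ddis <- function(drugs, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!"class" %in% names(drugs)) {
    abort("`drugs` must carry the latent `class` column from `simulate_drugs()`.")
  }
  if (config$n_types > config$n_classes^2) {
    abort(sprintf(
      "`n_types` (%d) exceeds the %d ordered class combinations available.",
      config$n_types, config$n_classes^2
    ))
  }
  with_seed(derive_seed(config$seed, "ddis"), {
    n <- nrow(drugs)
    n_avail <- n * (n - 1L)
    n_pairs <- min(config$n_pairs, n_avail)
    # index ordered pairs (a, b), a != b, then sample without replacement
    idx <- sample.int(n_avail, n_pairs)
    a <- ((idx - 1L) %/% (n - 1L)) + 1L
    b <- ((idx - 1L) %% (n - 1L)) + 1L
    b <- ifelse(b >= a, b + 1L, b)
    pairs <- tibble(
      drug_a = drugs$drug_id[a],
      drug_b = drugs$drug_id[b],
      type_label = planted_type(drugs$class[a], drugs$class[b],
                                config$n_classes, config$n_types)
    )
    pairs <- arrange(pairs, .data$drug_a, .data$drug_b)
    keep <- pairs |>
      count(.data$type_label) |>
      filter(.data$n >= config$pairs_per_type_min)
    dropped <- setdiff(unique(pairs$type_label), keep$type_label)
    if (length(dropped) > 0) {
      inform(sprintf(
        "Dropped %d DDI type(s) below the %d-pair floor: %s",
        length(dropped), config$pairs_per_type_min,
        paste(dropped, collapse = ", ")
      ))
    }
    filter(pairs, .data$type_label %in% keep$type_label)
  })
}
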
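# Readers and writers for every artifact format (UTF-8, tab-delimited,
# header row, '.' decimal, no quoting), the gold-standard DDI filtering
# rules, and the documented text interface to L1000-style signature
# exports. All writers are deterministic: identical inputs give
# byte-identical files.

stop_format <- function(path, msg) {
  abort(sprintf("Format error in '%s': %s", path, msg))
}

read_tsv_strict <- function(path, col_types = NULL) {
  # parsing issues surface as format errors below, not as readr warnings
  tbl <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = col_types)
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    stop_format(path, sprintf(
      "row %s, column %s: expected %s, got '%s' (%d problem(s) total)",
      p$row, p$col, p$expected, p$actual, nrow(probs)
    ))
  }
  tbl
}

# Read everything as character (with ragged-row detection), then convert the
# named columns with base R's correctly rounded as.numeric so that values
# written at full precision round-trip bit-exactly.
read_tsv_exact <- function(path, numeric_pattern) {
  tbl <- read_tsv_strict(path, col_types = readr::cols(.default = "c"))
  for (cn in grep(numeric_pattern, names(tbl), value = TRUE, perl = TRUE)) {
    v <- suppressWarnings(as.numeric(tbl[[cn]]))
    bad <- which(is.na(v) & !is.na(tbl[[cn]]))
    if (length(bad) > 0) {
      stop_format(path, sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        tbl[[cn]][bad[1]], bad[1], cn
      ))
    }
    miss <- which(is.na(v))
    if (length(miss) > 0) {
      stop_format(path, sprintf("missing value at row %d, column '%s'",
                                miss[1], cn))
    }
    tbl[[cn]] <- v
  }
  tbl
}

#' Read / write a drug table
#'
#' The drug-table format is tab-delimited text with a header row: columns
#' `drug_id`, `smiles`, signature columns `g1..gD` (D constant across
#' rows), and optionally fingerprint columns `fp1..fpB` and a latent
#' `class` column (as written for simulated tables). Writing then reading
#' reproduces all values to full precision.
#'
#' @param path File path.
#' @return A tibble, one row per drug.
#' @export
read_drug_table <- function(path) {
  tbl <- read_tsv_exact(path, "^(g|fp)[0-9]+$|^class$")
  need <- c("drug_id", "smiles")
  if (!all(need %in% names(tbl))) {
    stop_format(path, sprintf("missing required column(s): %s",
                              paste(setdiff(need, names(tbl)), collapse = ", ")))
  }
  gcols <- grep("^g[0-9]+$", names(tbl), value = TRUE)
  if (length(gcols) == 0) {
    stop_format(path, "no signature columns (g1, g2, ...) present")
  }
  dup <- tbl$drug_id[duplicated(tbl$drug_id)]
  if (length(dup) > 0) {
    stop_format(path, sprintf("duplicate drug_id(s): %s",
                              paste(unique(dup), collapse = ", ")))
  }
  if ("class" %in% names(tbl)) tbl$class <- as.integer(tbl$class)
  tbl$drug_id <- as.character(tbl$drug_id)
  tbl
}

#' @rdname read_drug_table
#' @param table Drug table to write.
#' @export
write_drug_table <- function(table, path) {
  stopifnot(is.data.frame(table), all(c("drug_id", "smiles") %in% names(table)))
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read / write a typed DDI list
#'
#' Tab-delimited text with header `drug_a`, `drug_b`, `type_label`; each
#' row is one ordered pair. Any string is a valid type label.
#'
#' @param path File path.
#' @return A tibble of ordered pairs.
#' @export
read_ddi_list <- function(path) {
  tbl <- read_tsv_strict(path, col_types = readr::cols(.default = "c"))
  need <- c("drug_a", "drug_b", "type_label")
  if (!all(need %in% names(tbl))) {
    stop_format(path, sprintf("missing required column(s): %s",
                              paste(setdiff(need, names(tbl)), collapse = ", ")))
  }
  tbl[need]
}

#' @rdname read_ddi_list
#' @param pairs DDI pair tibble to write.
#' @export
write_ddi_list <- function(pairs, path) {
  stopifnot(all(c("drug_a", "drug_b", "type_label") %in% names(pairs)))
  readr::write_tsv(pairs[c("drug_a", "drug_b", "type_label")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read / write a similarity graph as an edge list
#'
#' Three-column tab-delimited text (`source_id`, `target_id`, `weight`)
#' listing every nonzero edge, self-loops included, sorted by source then
#' target id.
#'
#' @param path File path.
#' @return A `similarity_graph`.
#' @export
read_similarity_graph <- function(path) {
  edges <- read_tsv_exact(path, "^weight$")
  need <- c("source_id", "target_id", "weight")
  if (!all(need %in% names(edges))) {
    stop_format(path, "expected columns source_id, target_id, weight")
  }
  ids <- sort(unique(c(edges$source_id, edges$target_id)))
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  w[cbind(edges$source_id, edges$target_id)] <- edges$weight
  structure(list(drug_ids = ids, weights = w), class = "similarity_graph")
}

#' @rdname read_similarity_graph
#' @param graph A `similarity_graph` to write.
#' @export
write_similarity_graph <- function(graph, path) {
  stopifnot(inherits(graph, "similarity_graph"))
  readr::write_tsv(tidy(graph), path, progress = FALSE)
  invisible(path)
}

#' Read / write a feature (embedding) table
#'
#' Tab-delimited text: `drug_id` plus one numeric column per feature
#' dimension.
#'
#' @param path File path.
#' @return A feature tibble.
#' @export
read_feature_table <- function(path) {
  tbl <- read_tsv_exact(path, "^(?!drug_id$)")
  if (!"drug_id" %in% names(tbl)) {
    stop_format(path, "missing drug_id column")
  }
  tbl$drug_id <- as.character(tbl$drug_id)
  tbl
}

#' @rdname read_feature_table
#' @param features Feature tibble to write.
#' @export
write_feature_table <- function(features, path) {
  stopifnot("drug_id" %in% names(features))
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' Apply the gold-standard DDI filtering rules
#'
#' Reproduces, on any raw interaction list, the preparation order used for
#' curated DDI gold standards: (1) drop every pair involving a drug flagged
#' as multi-ingredient or biologic (proteins / peptides); (2) drop pairs
#' whose drugs lack a transcriptome signature (absent from the drug table);
#' (3) drop interaction types left with fewer than `min_pairs_per_type`
#' pairs (so each surviving type can appear in every cross-validation
#' fold). Each step's removals are itemized in a provenance report.
#'
#' @param raw_pairs Tibble of `drug_a`, `drug_b`, `type_label`.
#' @param drug_table Drug table defining which drugs have signatures.
#' @param exclusions Optional tibble of `drug_id` plus logical/0-1 columns
#'   `multi_ingredient` and `biologic`.
#' @param min_pairs_per_type Per-type pair floor (default 5).
#' @return A list of class `ddi_prepared`: `pairs` (the surviving tibble)
#'   and `report` (one row per step: `step`, `n_removed`, `n_remaining`,
#'   `details` list-column itemizing dropped drugs or types).
#' @export
prepare_ddi_dataset <- function(raw_pairs, drug_table, exclusions = NULL,
                                min_pairs_per_type = 5) {
  stopifnot(all(c("drug_a", "drug_b", "type_label") %in% names(raw_pairs)))
  min_pairs_per_type <- check_count(min_pairs_per_type, "min_pairs_per_type")
  pairs <- as_tibble(raw_pairs)
  n0 <- nrow(pairs)
  report <- tibble(
    step = character(), n_removed = integer(), n_remaining = integer(),
    details = list()
  )
  log_step <- function(step, removed_details, pairs) {
    report <<- dplyr::bind_rows(report, tibble(
      step = step,
      n_removed = n0 - nrow(pairs),
      n_remaining = nrow(pairs),
      details = list(removed_details)
    ))
    n0 <<- nrow(pairs)
    pairs
  }

  flagged <- character(0)
  if (!is.null(exclusions)) {
    stopifnot("drug_id" %in% names(exclusions))
    flag_cols <- intersect(c("multi_ingredient", "biologic"), names(exclusions))
    flagged <- exclusions$drug_id[
      rowSums(as.data.frame(exclusions[flag_cols]) == 1 |
                as.data.frame(exclusions[flag_cols]) == TRUE) > 0
    ]
  }
  pairs <- log_step(
    "flagged_drugs",
    sort(intersect(flagged, c(pairs$drug_a, pairs$drug_b))),
    filter(pairs, !(.data$drug_a %in% flagged) & !(.data$drug_b %in% flagged))
  )

  known <- drug_table$drug_id
  missing_drugs <- sort(setdiff(c(pairs$drug_a, pairs$drug_b), known))
  pairs <- log_step(
    "no_signature",
    missing_drugs,
    filter(pairs, .data$drug_a %in% known & .data$drug_b %in% known)
  )

  type_counts <- count(pairs, .data$type_label)
  rare <- type_counts$type_label[type_counts$n < min_pairs_per_type]
  pairs <- log_step(
    "rare_types",
    sort(rare),
    filter(pairs, !(.data$type_label %in% rare))
  )

  if (nrow(pairs) == 0) {
    abort("No DDI pairs survive the preparation filters.")
  }
  structure(list(pairs = pairs, report = report), class = "ddi_prepared")
}

#' @export
print.ddi_prepared <- function(x, ...) {
  cat(sprintf("<ddi_prepared> %d pairs, %d types\n",
              nrow(x$pairs), length(unique(x$pairs$type_label))))
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-14s removed %4d -> %d remaining\n",
                x$report$step[i], x$report$n_removed[i],
                x$report$n_remaining[i]))
  }
  invisible(x)
}

#' Import an L1000-style signature text export
#'
#' Consumes a pre-exported tab-delimited matrix of per-signature
#' landmark-gene values (`sig_id`, `g1..gD`) and a signature metadata
#' table (`sig_id`, `compound_id`, `cell_line`, `is_exemplar`, optionally
#' `smiles`). Rows are filtered to one cell line and to exemplar
#' signatures; a compound with several surviving signatures gets their
#' per-gene mean. Native GCTx/HDF5 parsing is deliberately not implemented:
#' this text boundary is the documented interface for real data.
#'
#' @param matrix_path Path to the signature matrix TSV.
#' @param metadata_path Path to the signature metadata TSV.
#' @param cell_line Cell line to keep (e.g. `"PC3"`).
#' @return A drug table: `drug_id`, `smiles`, `g1..gD`.
#' @export
import_l1000_signatures <- function(matrix_path, metadata_path, cell_line) {
  mat <- read_tsv_strict(matrix_path)
  if (!"sig_id" %in% names(mat)) stop_format(matrix_path, "missing sig_id column")
  gcols <- grep("^g[0-9]+$", names(mat), value = TRUE)
  if (length(gcols) == 0) {
    stop_format(matrix_path, "no landmark columns (g1, g2, ...) present")
  }
  meta <- read_tsv_strict(metadata_path)
  need <- c("sig_id", "compound_id", "cell_line", "is_exemplar")
  if (!all(need %in% names(meta))) {
    stop_format(metadata_path, sprintf("missing column(s): %s",
                                       paste(setdiff(need, names(meta)), collapse = ", ")))
  }
  keep <- meta |>
    filter(.data$cell_line == !!cell_line,
           .data$is_exemplar == TRUE | .data$is_exemplar == 1)
  joined <- dplyr::inner_join(keep, mat, by = "sig_id")
  if (nrow(joined) == 0) {
    abort(sprintf("No exemplar signatures for cell line '%s'.", cell_line))
  }
  has_smiles <- "smiles" %in% names(joined)
  out <- joined |>
    group_by(.data$compound_id) |>
    summarise(
      smiles = if (has_smiles) dplyr::first(.data$smiles) else "*",
      across(all_of(gcols), mean),
      .groups = "drop"
    ) |>
    dplyr::rename(drug_id = "compound_id") |>
    arrange(.data$drug_id)
  out
}
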
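# Dataset curation: a four-step cleaning pipeline for structure-property
# tables. Steps, in order:
#   1. drop records with a missing label or missing SMILES;
#   2. canonicalize SMILES and resolve duplicate structures (mean label when
#      the group's label range is within a tolerance, whole group removed
#      otherwise);
#   3. drop inorganic (carbon-free) molecules;
#   4. drop molecules whose feature bundle (fingerprint + descriptors) cannot
#      be built.
# Every removal is tallied in a curation report so the cleaning is auditable.

#' Assemble molecule records
#'
#' Light constructor for the record table consumed by [clean_dataset()].
#'
#' @param smiles character vector of raw SMILES.
#' @param label numeric property labels (log10 mol/L for log S, dimensionless
#'   log10 ratios for log P / log D, log10 cm/s for log Papp).
#' @param name optional identifiers (e.g. drug names).
#' @return data.frame with columns `raw_smiles`, `label`, `name`.
#' @export
molecule_records <- function(smiles, label, name = NULL) {
  if (is.null(name)) name <- rep(NA_character_, length(smiles))
  stopifnot(length(smiles) == length(label), length(name) == length(smiles))
  data.frame(raw_smiles = as.character(smiles), label = as.numeric(label),
             name = as.character(name), stringsAsFactors = FALSE)
}

new_curation_report <- function(n_input = 0L, n_unparsable = 0L, n_unlabeled = 0L,
                                n_inorganic = 0L, n_duplicate_merged = 0L,
                                n_duplicate_conflict_removed = 0L,
                                n_featurization_failed = 0L, n_output = 0L) {
  structure(
    list(n_input = n_input, n_unparsable = n_unparsable, n_unlabeled = n_unlabeled,
         n_inorganic = n_inorganic, n_duplicate_merged = n_duplicate_merged,
         n_duplicate_conflict_removed = n_duplicate_conflict_removed,
         n_featurization_failed = n_featurization_failed, n_output = n_output),
    class = "bcs_curation_report"
  )
}

#' @export
print.bcs_curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  input records:                 %d\n", x$n_input))
  cat(sprintf("  removed, missing label:        %d\n", x$n_unlabeled))
  cat(sprintf("  removed, unparsable SMILES:    %d\n", x$n_unparsable))
  cat(sprintf("  merged duplicates (k-1 each):  %d\n", x$n_duplicate_merged))
  cat(sprintf("  removed, conflicting dups:     %d\n", x$n_duplicate_conflict_removed))
  cat(sprintf("  removed, inorganic:            %d\n", x$n_inorganic))
  cat(sprintf("  removed, featurization failed: %d\n", x$n_featurization_failed))
  cat(sprintf("  output records:                %d\n", x$n_output))
  invisible(x)
}

# Count conservation: input minus all removals (merges count k-1) must equal
# output. Used as an internal assertion and directly testable.
curation_report_consistent <- function(r) {
  r$n_input - r$n_unlabeled - r$n_unparsable - r$n_duplicate_merged -
    r$n_duplicate_conflict_removed - r$n_inorganic - r$n_featurization_failed ==
    r$n_output
}

#' Merge duplicate structure entries
#'
#' Groups records by canonical SMILES. Groups whose label range (max - min)
#' is at most `conflict_threshold` collapse to a single record carrying the
#' arithmetic-mean label; groups exceeding the threshold are judged
#' irreconcilable measurements and removed entirely. Singletons pass through.
#'
#' The default threshold of 0.5 log units reflects the typical inter-laboratory
#' spread of replicate solubility measurements for one compound.
#'
#' @param records data.frame with columns `canonical_smiles`, `label` (and
#'   optionally `name`).
#' @param conflict_threshold maximum tolerated label range within a duplicate
#'   group, in label (log) units; must be > 0.
#' @return list with `records` (deduplicated data.frame) and counts
#'   `n_merged` (sum of k-1 over merged groups) and `n_conflict_removed`
#'   (total records dropped from conflicting groups).
#' @export
merge_duplicates <- function(records, conflict_threshold = 0.5) {
  stopifnot(is.data.frame(records), "canonical_smiles" %in% names(records),
            "label" %in% names(records))
  if (!is.numeric(conflict_threshold) || conflict_threshold <= 0) {
    stop_bcstools("conflict_threshold must be > 0", "bcstools_non_positive_input_error")
  }
  if (nrow(records) == 0L) {
    return(list(records = records, n_merged = 0L, n_conflict_removed = 0L))
  }
  grp <- split(seq_len(nrow(records)), records$canonical_smiles)
  keep_rows <- list()
  n_merged <- 0L
  n_conflict <- 0L
  for (idx in grp) {
    if (length(idx) == 1L) {
      keep_rows[[length(keep_rows) + 1L]] <- records[idx, , drop = FALSE]
      next
    }
    labs <- records$label[idx]
    if (diff(range(labs)) <= conflict_threshold) {
      row <- records[idx[1L], , drop = FALSE]
      row$label <- mean(labs)
      keep_rows[[length(keep_rows) + 1L]] <- row
      n_merged <- n_merged + length(idx) - 1L
    } else {
      n_conflict <- n_conflict + length(idx)
    }
  }
  out <- if (length(keep_rows)) do.call(rbind, keep_rows)
         else records[0L, , drop = FALSE]
  # canonical-SMILES order makes the result independent of input record order
  out <- out[order(out$canonical_smiles), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, n_merged = n_merged, n_conflict_removed = n_conflict)
}

#' Clean a structure-property dataset
#'
#' Applies the four curation steps in order (missing data, duplicate
#' resolution after canonicalization, inorganic removal, featurization check)
#' and returns the cleaned dataset together with a per-step audit report.
#' Cleaning is idempotent and independent of input record order.
#'
#' @param records data.frame from [molecule_records()] or [read_property_csv()]
#'   with columns `raw_smiles` (or `smiles`), `label`, optional `name`.
#' @param endpoint one of `"logS"`, `"logP"`, `"logD"`, `"logPapp"`.
#' @param conflict_threshold see [merge_duplicates()].
#' @param keep_largest_fragment strip salts/mixtures to their largest organic
#'   fragment before canonicalization (default `TRUE`).
#' @param check_featurization run curation step 4 (attempt fingerprint and
#'   descriptor generation, dropping failures). When `TRUE` the returned
#'   dataset already carries its feature matrices.
#' @return list with `dataset` (a [property_dataset()]) and `report`
#'   (a curation report).
#' @export
clean_dataset <- function(records, endpoint = c("logS", "logP", "logD", "logPapp"),
                          conflict_threshold = 0.5, keep_largest_fragment = TRUE,
                          check_featurization = TRUE) {
  endpoint <- match.arg(endpoint)
  if (is.data.frame(records) && "smiles" %in% names(records) &&
      !"raw_smiles" %in% names(records)) {
    names(records)[names(records) == "smiles"] <- "raw_smiles"
  }
  stopifnot(is.data.frame(records), all(c("raw_smiles", "label") %in% names(records)))
  if (!"name" %in% names(records)) records$name <- NA_character_
  if (nrow(records) == 0L) {
    stop_bcstools("no input records", "bcstools_empty_dataset_error")
  }
  rep0 <- new_curation_report(n_input = nrow(records))

  # step 1: missing label / missing SMILES
  no_smiles <- is.na(records$raw_smiles) | !nzchar(trimws(records$raw_smiles))
  no_label <- is.na(records$label) | !is.finite(records$label)
  rep0$n_unlabeled <- sum(no_label & !no_smiles)
  rep0$n_unparsable <- sum(no_smiles)  # no structure at all: counted as unparsable
  records <- records[!no_smiles & !no_label, , drop = FALSE]

  # step 2a: canonicalize; parse failures are counted, not fatal
  records$canonical_smiles <- canonicalize_smiles(
    records$raw_smiles, strict = FALSE,
    keep_largest_fragment = keep_largest_fragment
  )
  bad <- is.na(records$canonical_smiles)
  rep0$n_unparsable <- rep0$n_unparsable + sum(bad)
  records <- records[!bad, , drop = FALSE]

  # step 2b: duplicate resolution on canonical structure
  md <- merge_duplicates(records, conflict_threshold)
  records <- md$records
  rep0$n_duplicate_merged <- md$n_merged
  rep0$n_duplicate_conflict_removed <- md$n_conflict_removed

  # step 3: inorganic removal
  org <- is_organic(records$canonical_smiles)
  rep0$n_inorganic <- sum(!org)
  records <- records[org, , drop = FALSE]

  # step 4: featurization check
  features <- NULL
  if (check_featurization && nrow(records) > 0L) {
    fz <- try_featurize(records$canonical_smiles)
    rep0$n_featurization_failed <- sum(!fz$ok)
    records <- records[fz$ok, , drop = FALSE]
    if (nrow(records) > 0L) {
      features <- list(
        fingerprint = fz$fingerprint[fz$ok, , drop = FALSE],
        descriptors = fz$descriptors[fz$ok, , drop = FALSE]
      )
    }
  }

  rep0$n_output <- nrow(records)
  stopifnot(curation_report_consistent(rep0))
  if (nrow(records) == 0L) {
    stop_bcstools("curation removed every record", "bcstools_empty_dataset_error")
  }
  rownames(records) <- NULL
  ds <- property_dataset(records, endpoint = endpoint, features = features)
  list(dataset = ds, report = rep0)
}

#' Read a structure-property CSV
#'
#' Expects columns for the SMILES and the numeric label, plus an optional
#' identifier column.
#'
#' @param path CSV file path.
#' @param smiles_col,value_col,name_col column names.
#' @return data.frame suitable for [clean_dataset()].
#' @export
read_property_csv <- function(path, smiles_col = "smiles", value_col = "value",
                              name_col = "name") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(smiles_col, value_col) %in% names(df))) {
    stop_bcstools(
      sprintf("CSV must contain columns '%s' and '%s'", smiles_col, value_col),
      "bcstools_parse_error"
    )
  }
  molecule_records(
    smiles = df[[smiles_col]],
    label = df[[value_col]],
    name = if (name_col %in% names(df)) df[[name_col]] else NULL
  )
}

#' Write a curated dataset and its audit report
#'
#' @param cleaned result of [clean_dataset()].
#' @param csv_path output CSV (canonical_smiles, label, name).
#' @param report_path optional JSON path for the curation report.
#' @return invisibly, `csv_path`.
#' @export
write_curated <- function(cleaned, csv_path, report_path = NULL) {
  rec <- cleaned$dataset$records
  utils::write.csv(rec[, c("canonical_smiles", "label", "name")], csv_path,
                   row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(unclass(cleaned$report), report_path, auto_unbox = TRUE)
  }
  invisible(csv_path)
}
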
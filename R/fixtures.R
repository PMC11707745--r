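# Bundled external-validation fixtures: the printed validation tables
# (transcribed verbatim) and the decision-rule cutoffs, shipped as plain-text
# files under inst/extdata and checksummed so silent edits are caught.

fixture_file <- function(name) {
  path <- system.file("extdata", name, package = "bcstools")
  if (!nzchar(path)) {
    stop_bcstools(sprintf("bundled fixture file '%s' not found", name),
                  "bcstools_unknown_fixture_error")
  }
  path
}

# md5 checksums of the shipped fixture files, frozen at packaging time.
.fixture_md5 <- c(
  "table9.csv" = "c59f22ed29cffaf782fed104dd714708",
  "validation_tables.json" = "7804d5ffddc51f781fc10097a24fa82d",
  "cutoffs.json" = "27f195757ea55811c4ce513e2655651b"
)

#' Verify bundled fixture integrity
#'
#' Compares the md5 checksum of every shipped fixture file against the value
#' frozen at packaging time.
#'
#' @return named logical vector, `TRUE` where the file is intact.
#' @export
fixture_checksums <- function() {
  vapply(names(.fixture_md5), function(f) {
    unname(tools::md5sum(fixture_file(f))) == .fixture_md5[[f]]
  }, TRUE)
}

#' Load a bundled validation fixture
#'
#' Available fixtures:
#' * `"table9"`: the 43-drug human jejunal permeability validation table
#'   (drug name as printed and normalized, reference BCS class, predicted
#'   log P / log D / log Papp). Carries the table's printed cutoffs as the
#'   `"printed_cutoffs"` attribute.
#' * `"table5"`: 2x2 solubility confusion counts (dose-number rule, 278 drugs).
#' * `"table6"`, `"table7"`, `"table8"`: 2x2 permeability confusion counts for
#'   the log P / log D / log Papp bases (222 drugs).
#' * `"table10"`: 4x4 BCS class confusion counts (206 drugs; rows predicted,
#'   columns true).
#' * `"cutoffs"`: the default [cutoff_set()].
#'
#' @param name fixture name.
#' @return a data.frame (`table9`), an integer matrix (confusion tables), or a
#'   `bcs_cutoffs` object.
#' @export
load_fixture <- function(name = c("table5", "table6", "table7", "table8",
                                  "table9", "table10", "cutoffs")) {
  if (length(name) != 1L || !name %in% c("table5", "table6", "table7", "table8",
                                         "table9", "table10", "cutoffs")) {
    stop_bcstools(sprintf("unknown fixture '%s'", paste(name, collapse = ",")),
                  "bcstools_unknown_fixture_error")
  }
  if (name == "table9") {
    df <- utils::read.csv(fixture_file("table9.csv"), stringsAsFactors = FALSE)
    df$bcs_class <- as.integer(df$bcs_class)
    tabs <- jsonlite::fromJSON(fixture_file("validation_tables.json"))
    pc <- tabs$table9_printed_cutoffs
    attr(df, "printed_cutoffs") <- c(logP = pc$logP, logD = pc$logD,
                                     logPapp = pc$logPapp)
    return(df)
  }
  if (name == "cutoffs") {
    co <- jsonlite::fromJSON(fixture_file("cutoffs.json"))
    return(cutoff_set(logP_cutoff = co$logP_cutoff, logD_cutoff = co$logD_cutoff,
                      logPapp_cutoff = co$logPapp_cutoff,
                      usp_solubility_cutoff = co$usp_solubility_cutoff,
                      D0_boundary = co$D0_boundary))
  }
  tabs <- jsonlite::fromJSON(fixture_file("validation_tables.json"))
  entry <- tabs[[name]]
  counts <- matrix(as.integer(entry$counts), nrow = nrow(entry$counts),
                   byrow = FALSE)
  if (name == "table10") {
    dimnames(counts) <- list(predicted = 1:4, true = 1:4)
  } else {
    dimnames(counts) <- list(true = c("high", "low"),
                             predicted = c("high", "low"))
  }
  attr(counts, "description") <- entry$description
  counts
}
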
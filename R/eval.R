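# Confusion-matrix evaluation for binary solubility/permeability
# classification and the 4-class BCS prediction.

#' Binary confusion matrix with derived rates
#'
#' Counts are arranged true x predicted over the levels `c("high","low")`.
#' Derived rates: total accuracy (trace/total), per-class accuracy (row-wise
#' recall), precision (column-wise), sensitivity (recall of "high") and
#' specificity (recall of "low").
#'
#' @param true_labels,pred_labels equal-length vectors over `c("high","low")`.
#' @return object of class `bcs_binary_confusion`.
#' @export
binary_confusion <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels) || length(true_labels) == 0L) {
    stop_bcstools("label vectors must have equal nonzero length",
                  "bcstools_length_mismatch_error")
  }
  lv <- c("high", "low")
  stopifnot(all(true_labels %in% lv), all(pred_labels %in% lv))
  counts <- table(factor(true_labels, lv), factor(pred_labels, lv))
  binary_confusion_from_counts(unclass(matrix(as.integer(counts), 2L, 2L,
                                              dimnames = list(true = lv, predicted = lv))))
}

#' @rdname binary_confusion
#' @param counts 2x2 integer matrix, rows = true `c("high","low")`, columns =
#'   predicted; used to evaluate published confusion tables directly.
#' @export
binary_confusion_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  counts <- matrix(as.integer(counts), 2L, 2L,
                   dimnames = list(true = c("high", "low"),
                                   predicted = c("high", "low")))
  total <- sum(counts)
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  structure(
    list(
      counts = counts,
      n = total,
      total_accuracy = sum(diag(counts)) / total,
      class_accuracy = diag(counts) / row_tot,     # row-wise (recall per class)
      precision = diag(counts) / col_tot,          # column-wise
      sensitivity = counts["high", "high"] / row_tot["high"],
      specificity = counts["low", "low"] / row_tot["low"]
    ),
    class = "bcs_binary_confusion"
  )
}

#' @export
print.bcs_binary_confusion <- function(x, ...) {
  cat("Binary confusion (true x predicted)\n")
  print(x$counts)
  cat(sprintf("total accuracy %.1f%%; high %.1f%%, low %.1f%%; precision high %.1f%%, low %.1f%%\n",
              100 * x$total_accuracy, 100 * x$class_accuracy["high"],
              100 * x$class_accuracy["low"], 100 * x$precision["high"],
              100 * x$precision["low"]))
  invisible(x)
}

# BCS class pairs that share neither the solubility nor the permeability
# attribute: 1<->4 and 2<->3.
bcs_total_miss_pairs <- cbind(c(1L, 4L, 2L, 3L), c(4L, 1L, 3L, 2L))

#' Four-class BCS confusion matrix
#'
#' Beyond the raw 4x4 counts, summarizes the prediction quality by attribute
#' agreement: *exact* (both the solubility and permeability attribute correct,
#' i.e. the diagonal), *total miss* (both attributes wrong — only the class
#' pairs 1/4 and 2/3 share neither attribute), and *partial* (exactly one
#' attribute correct — everything else). The three fractions sum to 1.
#'
#' @param true4,pred4 equal-length integer vectors over `1:4`.
#' @return object of class `bcs_bcs_confusion`.
#' @export
bcs_confusion <- function(true4, pred4) {
  if (length(true4) != length(pred4) || length(true4) == 0L) {
    stop_bcstools("label vectors must have equal nonzero length",
                  "bcstools_length_mismatch_error")
  }
  stopifnot(all(true4 %in% 1:4), all(pred4 %in% 1:4))
  counts <- table(factor(true4, 1:4), factor(pred4, 1:4))
  bcs_confusion_from_counts(matrix(as.integer(counts), 4L, 4L,
                                   dimnames = list(true = 1:4, predicted = 1:4)))
}

#' @rdname bcs_confusion
#' @param counts 4x4 integer count matrix. Orientation does not affect the
#'   exact/partial/miss decomposition (the miss cell set is symmetric).
#' @export
bcs_confusion_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 4L), all(counts >= 0))
  dn <- if (is.null(dimnames(counts))) list(true = 1:4, predicted = 1:4)
        else dimnames(counts)
  counts <- matrix(as.integer(counts), 4L, 4L, dimnames = dn)
  total <- sum(counts)
  exact <- sum(diag(counts))
  miss <- sum(counts[bcs_total_miss_pairs])
  structure(
    list(
      counts = counts,
      n = total,
      exact_count = exact,
      total_miss_count = miss,
      exact_fraction = exact / total,
      partial_fraction = (total - exact - miss) / total,
      total_miss_fraction = miss / total
    ),
    class = "bcs_bcs_confusion"
  )
}

#' @export
print.bcs_bcs_confusion <- function(x, ...) {
  cat("BCS 4-class confusion\n")
  print(x$counts)
  cat(sprintf("exact %.1f%% (%d), partial %.1f%%, total miss %.1f%% (%d) of %d\n",
              100 * x$exact_fraction, x$exact_count, 100 * x$partial_fraction,
              100 * x$total_miss_fraction, x$total_miss_count, x$n))
  invisible(x)
}

#' Evaluate permeability classification on the jejunal-permeability table
#'
#' Re-runs the permeability decision rule over the bundled 43-drug human
#' jejunal permeability validation table: the reference BCS class is mapped to
#' the permeability attribute (classes 1/2 high, 3/4 low), each printed
#' prediction is classified against the cutoff for the chosen basis, and the
#' fraction of agreements is the accuracy.
#'
#' By default the comparison uses the cutoffs printed in the table header
#' (1.720 / -0.195 / -5.097) and the strict boundary convention
#' (`boundary = "gt"`), which is the arithmetic that reproduces the published
#' per-basis accuracies; the boundary only matters for the single reference
#' drug whose prediction equals the cutoff.
#'
#' @param fixture the table as returned by `load_fixture("table9")` (default).
#' @param basis `"logPapp"`, `"logP"` or `"logD"`.
#' @param cutoffs optional [cutoff_set()] override; default: the fixture's
#'   printed cutoffs.
#' @param boundary boundary convention passed to [classify_permeability()].
#' @return list with `verdicts` (per-drug data.frame), `n_correct`, `n`, and
#'   `accuracy`.
#' @export
evaluate_table9 <- function(fixture = load_fixture("table9"),
                            basis = c("logPapp", "logP", "logD"),
                            cutoffs = NULL, boundary = "gt") {
  basis <- match.arg(basis)
  if (is.null(cutoffs)) {
    pc <- attr(fixture, "printed_cutoffs")
    cutoffs <- cutoff_set(logP_cutoff = pc[["logP"]], logD_cutoff = pc[["logD"]],
                          logPapp_cutoff = pc[["logPapp"]])
  }
  value <- fixture[[paste0("pred_", basis)]]
  true_perm <- bcs_permeability_attribute(fixture$bcs_class)
  pred_perm <- classify_permeability(value, basis, cutoffs, boundary = boundary)
  verdicts <- data.frame(
    name = fixture$name, bcs_class = fixture$bcs_class,
    true_permeability = true_perm, value = value,
    predicted_permeability = pred_perm,
    correct = true_perm == pred_perm,
    stringsAsFactors = FALSE
  )
  list(verdicts = verdicts, n_correct = sum(verdicts$correct),
       n = nrow(verdicts), accuracy = mean(verdicts$correct))
}

#' Write a confusion object as CSV
#'
#' @param confusion a `bcs_binary_confusion` or `bcs_bcs_confusion`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_confusion_csv <- function(confusion, path) {
  utils::write.csv(as.data.frame.matrix(confusion$counts), path)
  invisible(path)
}
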
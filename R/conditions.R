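# Structured conditions. Every domain error is a subclass of "bcstools_error"
# so callers can catch the whole family or a specific failure mode.

stop_bcstools <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "bcstools_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

warn_bcstools <- function(msg, class) {
  warning(structure(
    class = c(class, "bcstools_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# condition classes used throughout:
#   bcstools_parse_error            invalid / unparsable SMILES
#   bcstools_featurization_error    fingerprint or descriptor generation failed
#   bcstools_embedding_error        3D conformer could not be generated
#   bcstools_empty_dataset_error    curation removed every record
#   bcstools_too_small_error        dataset/fold below minimum size
#   bcstools_degenerate_error       zero-variance labels (R^2 undefined)
#   bcstools_length_mismatch_error  unequal vector lengths
#   bcstools_non_positive_input_error  dose/solubility inputs must be > 0
#   bcstools_missing_model_error    required endpoint model not supplied
#   bcstools_unknown_fixture_error  unknown bundled fixture name
#   bcstools_missing_dose_warning   no dose given; USP solubility rule used
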
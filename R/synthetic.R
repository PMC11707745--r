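# Synthetic structure-property data. A small SMILES grammar (linear and
# branched alkyl chains, optionally decorated benzene/pyridine rings with
# O/N/halogen substituents) is enumerated exhaustively, deduplicated on
# canonical structure, and sampled. Labels are a deterministic function of the
# package's own descriptor panel plus Gaussian noise, so a competent regressor
# must recover the signal down to the noise floor. The default label is
# (3 * MW + 3 * TPSA) / 100: a monotone linear blend of molecular size and
# polarity whose recovery behaviour is stable across chemistry-toolkit
# versions, with a signal standard deviation (~1.3 log units) over noise
# (0.3) comparable to real log-scale property datasets. These molecules
# emulate the scale and feature structure of QSPR datasets, not realistic
# property chemistry.

synthetic_grammar_smiles <- function() {
  chains <- unlist(lapply(1:10, function(k) strrep("C", k)))
  caps <- c("", "O", "N", "Cl", "F", "Br", "C(=O)O", "C(=O)OC", "C(=O)N",
            "C#N", "OC", "OCC", "N(C)C", "S", "SC", "C(O)C")
  linear <- as.vector(outer(chains, caps, paste0))
  branched <- as.vector(outer(
    c("CC(C)", "CC(C)C", "CC(C)(C)", "CCC(C)", "CC(CC)"),
    c(caps, "CC", "CO", "CCO"), paste0
  ))
  short <- chains[1:8]
  ethers <- as.vector(outer(short, short, function(a, b) paste0(a, "O", b)))
  esters <- c(as.vector(outer(short, short, function(a, b) paste0(a, "C(=O)O", b))),
              as.vector(outer(short, short, function(a, b) paste0(a, "OC(=O)", b))))
  amines <- as.vector(outer(short, short, function(a, b) paste0(a, "N", b)))
  amides <- as.vector(outer(short, short, function(a, b) paste0(a, "C(=O)N", b)))

  subs <- c("C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl", "Br",
            "C(=O)O", "C#N", "S", "CO", "CCO", "OCC", "N(C)C", "C(C)C")
  rings <- c("c1ccccc1", "c1ccncc1")
  aro1 <- as.vector(outer(rings, subs, function(r, s) paste0(s, r)))
  # benzyl-capped chains
  benzylic <- paste0("c1ccccc1", linear[1:100])
  # disubstituted benzenes (para and meta) and pyridines (2,5)
  aro2 <- c(
    unlist(lapply(subs, function(s1) paste0(s1, "c1ccc(", subs, ")cc1"))),
    unlist(lapply(subs, function(s1) paste0(s1, "c1cccc(", subs, ")c1"))),
    unlist(lapply(subs, function(s1) paste0(s1, "c1ccc(", subs[1:6], ")cn1")))
  )
  # 1,3,5-trisubstituted benzenes
  aro3 <- unlist(lapply(subs, function(s1) {
    unlist(lapply(subs, function(s2) {
      paste0(s1, "c1cc(", s2, ")cc(", subs[1:8], ")c1")
    }))
  }))
  unique(c(linear, branched, ethers, esters, amines, amides,
           aro1, benzylic, aro2, aro3))
}

#' Generate a synthetic structure-property dataset
#'
#' Enumerates parseable SMILES from a fixed grammar, deduplicates on canonical
#' structure, samples `n_molecules` of them (seeded), computes the descriptor
#' panel, and assigns `label = label_fun(descriptors) + N(0, noise_sd)`.
#' The result is fully reproducible for a given seed, and the labels are
#' invariant to SMILES atom-order permutation because they depend only on
#' descriptors.
#'
#' With `curation_stress = TRUE` the function instead returns *raw* records
#' for exercising [clean_dataset()]: valid molecules plus planted defects (an
#' unlabeled record, an unparsable SMILES, a carbon-free molecule, a duplicate
#' pair with close labels, and a duplicate pair with conflicting labels),
#' described in the `planted` element.
#'
#' @param n_molecules number of molecules (>= 10).
#' @param endpoint which endpoint the labels emulate (metadata only).
#' @param noise_sd Gaussian label noise standard deviation (default 0.3, a
#'   realistic mid-range experimental error for log-scale property data).
#' @param seed integer seed (default 42).
#' @param label_fun `function(descriptor_matrix) -> numeric` deterministic
#'   signal; default `(3 * MW + 3 * TPSA) / 100`.
#' @param curation_stress return raw records with planted defects instead of a
#'   featurized dataset.
#' @param featurize attach fingerprint/descriptor matrices (default `TRUE`).
#' @return a [property_dataset()] (or, with `curation_stress`, a list with
#'   `records` and `planted`).
#' @export
generate_synthetic_dataset <- function(n_molecules = 2000L,
                                       endpoint = c("logS", "logP", "logD", "logPapp"),
                                       noise_sd = 0.3, seed = 42L,
                                       label_fun = NULL,
                                       curation_stress = FALSE,
                                       featurize = TRUE) {
  endpoint <- match.arg(endpoint)
  stopifnot(n_molecules >= 10L, noise_sd >= 0)
  if (is.null(label_fun)) {
    label_fun <- function(desc) (3 * desc[, "MW"] + 3 * desc[, "TPSA"]) / 100
  }
  pool <- synthetic_grammar_smiles()
  canon <- canonicalize_smiles(pool, strict = FALSE)
  canon <- unique(canon[!is.na(canon)])
  if (n_molecules > length(canon)) {
    stop_bcstools(sprintf("grammar yields only %d unique molecules", length(canon)),
                  "bcstools_too_small_error")
  }
  smiles <- withr::with_seed(seed, sample(canon, n_molecules))
  names(smiles) <- paste0("syn", seq_len(n_molecules))
  desc <- compute_descriptors(smiles)
  signal <- label_fun(desc)
  noise <- withr::with_seed(seed + 1L, stats::rnorm(n_molecules, 0, noise_sd))
  label <- as.numeric(signal + noise)

  if (curation_stress) {
    base <- data.frame(raw_smiles = unname(smiles), label = label,
                       name = names(smiles), stringsAsFactors = FALSE)
    dup_close <- data.frame(
      raw_smiles = c(base$raw_smiles[1L], base$raw_smiles[1L]),
      label = base$label[1L] + c(0.1, -0.1),
      name = c("dup_close_a", "dup_close_b"), stringsAsFactors = FALSE
    )
    dup_conflict <- data.frame(
      raw_smiles = c(base$raw_smiles[2L], base$raw_smiles[2L]),
      label = base$label[2L] + c(2, -2),
      name = c("dup_conflict_a", "dup_conflict_b"), stringsAsFactors = FALSE
    )
    defects <- data.frame(
      raw_smiles = c("O", "C1CC", NA_character_, base$raw_smiles[3L]),
      label = c(-1.0, -1.0, NA_real_, NA_real_),
      name = c("planted_inorganic", "planted_unparsable",
               "planted_missing_smiles", "planted_unlabeled"),
      stringsAsFactors = FALSE
    )
    records <- rbind(base, dup_close, dup_conflict, defects)
    rownames(records) <- NULL
    return(list(
      records = records,
      planted = list(
        inorganic = "planted_inorganic",
        unparsable = "planted_unparsable",
        missing_smiles = "planted_missing_smiles",
        unlabeled = "planted_unlabeled",
        duplicate_merged = c("dup_close_a", "dup_close_b"),
        duplicate_conflict = c("dup_conflict_a", "dup_conflict_b",
                               base$name[2L]),
        expected_output = n_molecules - 1L  # conflict group removes base row 2
      )
    ))
  }

  records <- data.frame(canonical_smiles = unname(smiles), label = label,
                        name = names(smiles), stringsAsFactors = FALSE)
  features <- NULL
  if (featurize) {
    fp <- compute_ecfp(smiles)
    if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
    features <- list(fingerprint = fp, descriptors = desc)
  }
  property_dataset(records, endpoint = endpoint, features = features)
}
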
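test_that("canonicalization maps equivalent SMILES to one string and is idempotent", {
  expect_equal(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  expect_equal(canonicalize_smiles("C1=CC=CC=C1"), canonicalize_smiles("c1ccccc1"))
  can <- canonicalize_smiles("N(C)C(=O)c1ccccc1")
  expect_identical(canonicalize_smiles(can), can)
})

test_that("canonicalization preserves stereochemistry and rejects invalid input", {
  l_ala <- canonicalize_smiles("C[C@H](N)C(=O)O")
  d_ala <- canonicalize_smiles("C[C@@H](N)C(=O)O")
  expect_false(l_ala == d_ala)
  expect_error(canonicalize_smiles("C1CC"), class = "bcstools_parse_error")
  expect_error(canonicalize_smiles(""), class = "bcstools_parse_error")
  expect_identical(canonicalize_smiles(c("CCO", "C1CC"), strict = FALSE)[2], NA_character_)
})

test_that("largest-fragment stripping keeps the organic part of salts", {
  expect_equal(canonicalize_smiles("CCO.[Na+]", keep_largest_fragment = TRUE),
               canonicalize_smiles("CCO"))
  expect_equal(canonicalize_smiles("[Cl-].CCN", keep_largest_fragment = TRUE),
               canonicalize_smiles("CCN"))
  # without stripping, the salt remains a distinct structure
  expect_false(canonicalize_smiles("CCO.[Na+]") == canonicalize_smiles("CCO"))
})

test_that("organic test requires at least one carbon atom", {
  expect_false(is_organic("O"))
  expect_true(is_organic("CCO"))
  expect_false(is_organic("[Na+].[Cl-]"))
  expect_true(is_organic("c1ccccc1"))
  expect_false(is_organic("[Co+2]"))   # cobalt is not carbon
  expect_true(is_organic("[CH3-]"))
})

test_that("duplicate groups merge to the arithmetic mean or are removed on conflict", {
  rec <- data.frame(
    canonical_smiles = c("CCO", "CCO", "CCN", "CCC", "CCC"),
    label = c(-2.0, -2.2, -3.3, -2.0, -4.0),
    stringsAsFactors = FALSE
  )
  out <- merge_duplicates(rec, conflict_threshold = 0.5)
  expect_equal(out$n_merged, 1L)
  expect_equal(out$n_conflict_removed, 2L)
  expect_equal(out$records$label[out$records$canonical_smiles == "CCO"], -2.1)
  expect_equal(out$records$label[out$records$canonical_smiles == "CCN"], -3.3)
  expect_false("CCC" %in% out$records$canonical_smiles)
  expect_error(merge_duplicates(rec, conflict_threshold = 0),
               class = "bcstools_non_positive_input_error")
})

test_that("groups of three or more duplicates use the whole-group range criterion", {
  rec <- data.frame(canonical_smiles = rep("CCO", 3), label = c(-2.0, -2.2, -2.4))
  out <- merge_duplicates(rec, 0.5)
  expect_equal(out$records$label, -2.2)
  expect_equal(out$n_merged, 2L)
  rec$label <- c(-2.0, -2.2, -2.6)  # range 0.6 > 0.5: remove all three
  out <- merge_duplicates(rec, 0.5)
  expect_equal(nrow(out$records), 0L)
  expect_equal(out$n_conflict_removed, 3L)
})

test_that("cleaning applies the four steps in order with a conserved report", {
  rec <- molecule_records(
    smiles = c("CCO", "OCC", "CCN", "O", "C1CC", "CCCC", "CCC", "CCC"),
    label = c(-2.0, -2.2, -3.3, -1.0, -1.0, NA, -2.0, -4.0),
    name = c("a", "b", "c", "water", "bad", "nolabel", "d1", "d2")
  )
  out <- clean_dataset(rec, "logS")
  r <- out$report
  expect_equal(r$n_input, 8L)
  expect_equal(r$n_unlabeled, 1L)
  expect_equal(r$n_unparsable, 1L)
  expect_equal(r$n_duplicate_merged, 1L)
  expect_equal(r$n_duplicate_conflict_removed, 2L)
  expect_equal(r$n_inorganic, 1L)
  expect_equal(r$n_output, 2L)
  expect_true(r$n_input - r$n_unlabeled - r$n_unparsable - r$n_duplicate_merged -
                r$n_duplicate_conflict_removed - r$n_inorganic -
                r$n_featurization_failed == r$n_output)
  expect_setequal(out$dataset$records$canonical_smiles, c("CCO", "CCN"))
  expect_equal(out$dataset$records$label[out$dataset$records$canonical_smiles == "CCO"],
               -2.1)
})

test_that("cleaning is idempotent and independent of record order", {
  rec <- molecule_records(
    smiles = c("CCO", "OCC", "CCN", "O", "CCCO", "c1ccccc1O"),
    label = c(-2.0, -2.2, -3.3, -1.0, -2.5, -1.7)
  )
  out1 <- clean_dataset(rec, "logS")
  # re-clean the cleaned output
  rec2 <- out1$dataset$records
  rec2$raw_smiles <- rec2$canonical_smiles
  out2 <- clean_dataset(rec2, "logS")
  expect_equal(out2$dataset$records$canonical_smiles,
               out1$dataset$records$canonical_smiles)
  expect_equal(out2$dataset$records$label, out1$dataset$records$label)
  expect_equal(sum(unlist(out2$report[c("n_unlabeled", "n_unparsable",
                                        "n_duplicate_merged",
                                        "n_duplicate_conflict_removed",
                                        "n_inorganic",
                                        "n_featurization_failed")])), 0L)
  # permuted input gives the same record set
  out3 <- clean_dataset(rec[c(5, 3, 1, 6, 2, 4), ], "logS")
  expect_equal(out3$dataset$records$canonical_smiles,
               out1$dataset$records$canonical_smiles)
  expect_equal(out3$dataset$records$label, out1$dataset$records$label)
  # no duplicated canonical structures in the output
  expect_false(any(duplicated(out1$dataset$records$canonical_smiles)))
})

test_that("an all-bad input raises an empty-dataset error", {
  rec <- molecule_records(smiles = c("O", "C1CC"), label = c(-1, -1))
  expect_error(clean_dataset(rec, "logS"), class = "bcstools_empty_dataset_error")
})

test_that("CSV reader/writer round-trips a curated dataset with its report", {
  csv_in <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c("CCO", "CCN", "O"), value = c(-2, -3, -1),
                       name = c("eth", "amine", "water")),
            csv_in, row.names = FALSE)
  rec <- read_property_csv(csv_in)
  out <- clean_dataset(rec, "logS")
  csv_out <- withr::local_tempfile(fileext = ".csv")
  json_out <- withr::local_tempfile(fileext = ".json")
  write_curated(out, csv_out, json_out)
  back <- read.csv(csv_out)
  expect_equal(nrow(back), 2L)
  rep_back <- jsonlite::fromJSON(json_out)
  expect_equal(rep_back$n_inorganic, 1L)
})
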
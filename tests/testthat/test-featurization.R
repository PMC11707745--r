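test_that("fingerprints have the configured length and are deterministic", {
  fp <- compute_ecfp("CCO")
  expect_length(fp, 1024)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(fp, compute_ecfp("CCO"))
  expect_identical(fp, compute_ecfp("OCC"))           # atom-order permutation
  expect_true(any(compute_ecfp("C") != compute_ecfp("c1ccccc1")))
  expect_length(compute_ecfp("CCO", n_bits = 2048), 2048)
  expect_error(compute_ecfp("CCO", n_bits = 1000),
               class = "bcstools_featurization_error")
  expect_error(compute_ecfp("C1CC"), class = "bcstools_featurization_error")
})

test_that("fingerprint popcount is invariant under SMILES permutation and folding ORs blocks", {
  variants <- c("c1ccccc1CCO", "OCCc1ccccc1", "C(O)Cc1ccccc1")
  pops <- vapply(variants, function(s) sum(compute_ecfp(s)), 0)
  expect_true(all(pops == pops[1]))
  # folding can only lose bits relative to the wider fingerprint
  wide <- sum(compute_ecfp("CCOc1ccncc1", n_bits = 4096))
  folded <- sum(compute_ecfp("CCOc1ccncc1", n_bits = 1024))
  expect_true(folded <= wide)
  expect_true(folded > 0)
})

test_that("descriptor panel covers MW and TPSA with correct reference values", {
  w <- compute_descriptors("O")
  expect_equal(w[["MW"]], 18.02, tolerance = 1e-3)
  expect_equal(compute_descriptors("c1ccccc1")[["TPSA"]], 0)
  expect_identical(compute_descriptors("CCN"), compute_descriptors("CCN"))
  expect_equal(compute_descriptors("OCC"), compute_descriptors("CCO")) # canonical invariance
  expect_true(all(is.finite(compute_descriptors(c("CCO", "C", "[NH4+]")))))
  sub <- compute_descriptors("CCO", descriptor_set = c("MW", "TPSA"))
  expect_named(sub, c("MW", "TPSA"))
  expect_error(compute_descriptors("CCO", descriptor_set = "NoSuch"),
               class = "bcstools_featurization_error")
})

test_that("structural descriptors count atoms, bonds, rings and charges correctly", {
  m <- compute_descriptors(c("CCO", "c1ccccc1", "C[N+](C)(C)C", "CC(=O)[O-]", "C#N"))
  expect_equal(unname(m[, "NumHeavyAtoms"]), c(3, 6, 5, 4, 2))
  expect_equal(unname(m[, "NumBonds"]), c(2, 6, 4, 3, 1))
  expect_equal(unname(m[, "NumRings"]), c(0, 1, 0, 0, 0))
  expect_equal(unname(m[, "NumRingBonds"]), c(0, 6, 0, 0, 0))
  expect_equal(unname(m[, "NumAromaticAtoms"]), c(0, 6, 0, 0, 0))
  expect_equal(unname(m[, "NetCharge"]), c(0, 0, 1, -1, 0))
  expect_equal(unname(m[, "NumTripleBonds"]), c(0, 0, 0, 0, 1))
})

test_that("molecular graphs have one node per heavy atom and one edge per bond", {
  g <- build_graph("CC")
  expect_equal(nrow(g$node_features), 2L)
  expect_equal(nrow(g$edge_features), 1L)
  g1 <- build_graph("C")                       # degenerate graph accepted
  expect_equal(nrow(g1$node_features), 1L)
  expect_equal(nrow(g1$edge_features), 0L)
  expect_equal(ncol(g$node_features), 9L)
  expect_equal(ncol(g$edge_features), 4L)
})

test_that("benzene edges are all aromatic-ring conjugated and adjacency is symmetric", {
  g <- build_graph("c1ccccc1")
  expect_equal(nrow(g$node_features), 6L)
  expect_equal(nrow(g$edge_features), 6L)
  expect_true(all(g$edge_features[, "in_ring"] == 1))
  expect_true(all(g$edge_features[, "conjugated"] == 1))
  expect_true(all(g$node_features[, "aromatic"] == 1))
  expect_true(all(g$node_features[, "num_hydrogens"] == 1))
  expect_identical(g$adjacency, t(g$adjacency))
  expect_false(any(diag(g$adjacency)))
})

test_that("graph node/edge counts match the descriptor counts over a molecule batch", {
  ds <- generate_synthetic_dataset(25, seed = 3, featurize = FALSE)
  smiles <- ds$records$canonical_smiles
  desc <- compute_descriptors(smiles)
  for (i in seq_along(smiles)) {
    g <- build_graph(smiles[i])
    expect_equal(nrow(g$node_features), unname(desc[i, "NumHeavyAtoms"]))
    expect_equal(nrow(g$edge_features), unname(desc[i, "NumBonds"]))
  }
})

test_that("conformer embedding is seed-reproducible with sane geometry", {
  cf <- embed_conformer("CC", seed = 7)
  cf2 <- embed_conformer("CC", seed = 7)
  expect_identical(cf$positions, cf2$positions)
  expect_equal(cf$energy, cf2$energy)
  expect_equal(nrow(cf$positions), 8L)         # 2 heavy + 6 hydrogens
  expect_true(all(is.finite(cf$positions)))
  cc <- sqrt(sum((cf$positions[1, ] - cf$positions[2, ])^2))
  expect_gt(cc, 1.50); expect_lt(cc, 1.55)     # MMFF94 C-C single bond
  expect_error(embed_conformer("C1CC"), class = "bcstools_embedding_error")
})

test_that("bonded atoms in embedded conformers sit at chemically plausible distances", {
  for (smi in c("CCO", "c1ccccc1")) {
    cf <- embed_conformer(smi, seed = 1)
    g <- build_graph(smi)
    heavy <- which(rownames(cf$positions) != "H")
    for (k in seq_len(nrow(g$edges))) {
      d <- sqrt(sum((cf$positions[heavy[g$edges[k, 1]], ] -
                       cf$positions[heavy[g$edges[k, 2]], ])^2))
      expect_gt(d, 0.5); expect_lt(d, 3.0)
    }
  }
})

test_that("feature bundles assemble all representations", {
  fb <- featurize_molecule("CCO", conformer = TRUE, seed = 5)
  expect_s3_class(fb, "bcs_feature_bundle")
  expect_length(fb$fingerprint, 1024)
  expect_named(fb$descriptors)
  expect_s3_class(fb$graph, "bcs_molgraph")
  expect_s3_class(fb$conformer, "bcs_conformer")
  expect_true(all(is.finite(fb$descriptors)))
})

test_that("conformer SDF export writes readable records", {
  cfs <- embed_conformers(c("CC", "CCO"), seed = 2)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_conformer_sdf(cfs, c("CC", "CCO"), path)
  txt <- readLines(path)
  expect_equal(sum(txt == "$$$$"), 2L)
  expect_true(any(grepl("mmff94_energy", txt)))
})
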
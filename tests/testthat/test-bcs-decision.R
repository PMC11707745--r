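test_that("molar solubility converts to mg/mL through the molecular weight", {
  expect_equal(logS_to_Cs(0, 100), 100)
  expect_equal(logS_to_Cs(-3, 250), 0.25)
  guard <- logS_to_Cs(-20, 300)
  expect_gt(guard, 0); expect_true(is.finite(guard))
  expect_error(logS_to_Cs(-2, 0), class = "bcstools_non_positive_input_error")
})

test_that("dose number follows M0/(V0*Cs) and decreases in solubility", {
  expect_equal(dose_number(25, 0.1, 250), 1)
  expect_equal(dose_number(500, 0.1, 250), 20)
  cs <- seq(0.01, 10, length.out = 50)
  d0 <- vapply(cs, function(x) dose_number(200, x), 0)
  expect_true(all(diff(d0) < 0))
  expect_error(dose_number(-5, 0.1), class = "bcstools_non_positive_input_error")
  expect_error(dose_number(5, 0), class = "bcstools_non_positive_input_error")
})

test_that("the dose-number rule classifies the boundary as highly soluble", {
  expect_equal(classify_solubility(1), "high")
  expect_equal(classify_solubility(1.0001), "low")
  expect_equal(classify_solubility(20), "low")
  expect_equal(classify_solubility(c(0.2, 5)), c("high", "low"))
})

test_that("dose-free USP rule uses the 0.1 mg/mL cutoff with boundary high", {
  expect_equal(classify_solubility_usp(0.25), "high")
  expect_equal(classify_solubility_usp(0.01), "low")
  expect_equal(classify_solubility_usp(0.1), "high")
  expect_error(classify_solubility_usp(0), class = "bcstools_non_positive_input_error")
})

test_that("solubility classification is monotone in Cs for a fixed dose", {
  cs <- 10^seq(-4, 2, length.out = 100)
  cls <- classify_solubility(vapply(cs, function(x) dose_number(100, x), 0))
  # once high, always high as Cs increases
  expect_true(all(diff(cls == "high") >= 0))
})

test_that("permeability cutoffs classify the reference examples correctly", {
  expect_equal(classify_permeability(-4.809, "logPapp"), "high")   # metoprolol
  expect_equal(classify_permeability(-6.340, "logPapp"), "low")    # amoxicillin
  expect_equal(classify_permeability(1.821, "logP"), "high")
  # the reference drug defines the boundary: equal value is high by default
  expect_equal(classify_permeability(-0.1954, "logD"), "high")
  # strict convention pushes the boundary value to low
  expect_equal(classify_permeability(-0.1954, "logD", boundary = "gt"), "low")
})

test_that("ionization correction reduces logP by log10(2) at pH == pKa", {
  expect_equal(logD_from_logP(2.5, 4.0, pH = 4.0, species = "acid"),
               2.5 - log10(2), tolerance = 1e-9)
  expect_equal(logD_from_logP(1.0, 9.0, pH = 9.0, species = "base"),
               1.0 - log10(2), tolerance = 1e-9)
})

test_that("ionization correction vanishes in the un-ionized limit", {
  expect_equal(logD_from_logP(2.0, 10.0, pH = 4.0, species = "acid"), 2.0,
               tolerance = 1e-6)
  expect_equal(logD_from_logP(3.0, 4.0, pH = 10.0, species = "base"), 3.0,
               tolerance = 1e-6)
})

test_that("logD never exceeds logP over random parameter draws", {
  for (i in 1:200) {
    lp <- withr::with_seed(i, runif(1, -2, 6))
    pka <- withr::with_seed(i + 1000, runif(1, 0, 14))
    ph <- withr::with_seed(i + 2000, runif(1, 1, 12))
    sp <- if (i %% 2 == 0) "acid" else "base"
    expect_lte(logD_from_logP(lp, pka, ph, sp), lp)
  }
})

test_that("the class map is the expected bijection over the 2x2 attribute space", {
  expect_equal(assign_bcs("high", "high"), 1L)
  expect_equal(assign_bcs("low", "high"), 2L)
  expect_equal(assign_bcs("high", "low"), 3L)
  expect_equal(assign_bcs("low", "low"), 4L)
  grid <- expand.grid(sol = c("high", "low"), perm = c("high", "low"),
                      stringsAsFactors = FALSE)
  expect_setequal(assign_bcs(grid$sol, grid$perm), 1:4)
})

test_that("end-to-end prediction traces the dose-number decision", {
  # stub models: Cs = 10^logS * MW = 10^(-4.39794) * 250 = 0.01 mg/mL
  models <- list(logS = function(s) -4.39794, logPapp = function(s) -4.5)
  r <- predict_bcs("CCO", models, dose = dose_context(500, MW = 250))
  expect_equal(r$D0, 200, tolerance = 1e-4)
  expect_equal(r$solubility_class, "low")
  expect_equal(r$permeability_class, "high")
  expect_equal(r$bcs_class, 2L)
  # determinism
  r2 <- predict_bcs("CCO", models, dose = dose_context(500, MW = 250))
  expect_equal(r$properties, r2$properties)
  expect_equal(r$bcs_class, r2$bcs_class)
})

test_that("prediction falls back to the USP rule with a warning when no dose is given", {
  models <- list(logS = function(s) -1, logPapp = function(s) -6)
  expect_warning(r <- predict_bcs("CCO", models),
                 class = "bcstools_missing_dose_warning")
  expect_true(is.na(r$D0))
  expect_equal(r$solubility_class, "high")   # 10^-1 * 46 g/mol = 4.6 mg/mL
  expect_equal(r$permeability_class, "low")
  expect_equal(r$bcs_class, 3L)
})

test_that("prediction validates its inputs and model registry", {
  expect_error(predict_bcs("C1CC", list(logS = function(s) -1,
                                        logPapp = function(s) -5)),
               class = "bcstools_parse_error")
  expect_error(predict_bcs("CCO", list(logS = function(s) -1)),
               class = "bcstools_missing_model_error")
  expect_error(dose_context(-1), class = "bcstools_non_positive_input_error")
})

test_that("alternative permeability bases remain selectable", {
  models <- list(logS = function(s) -1, logP = function(s) 2.0,
                 logD = function(s) -1.0)
  r1 <- suppressWarnings(predict_bcs("CCO", models, perm_basis = "logP"))
  r2 <- suppressWarnings(predict_bcs("CCO", models, perm_basis = "logD"))
  expect_equal(r1$permeability_class, "high")   # 2.0 >= 1.72
  expect_equal(r2$permeability_class, "low")    # -1.0 < -0.1954
  expect_equal(r1$permeability_basis, "logP")
})

test_that("trained bundles plug into the end-to-end prediction", {
  ds <- shared_qspr_dataset()
  bundle <- train_regressor(ds, seed = 9)
  r <- suppressWarnings(predict_bcs("CCOc1ccccc1", list(
    logS = bundle, logPapp = function(s) -5.0
  )))
  expect_true(r$bcs_class %in% 1:4)
  expect_true(is.finite(r$properties[["logS"]]))
})
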
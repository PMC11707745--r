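# BCS decision layer: converts property values (predicted or measured) into a
# solubility class, a permeability class, and the provisional BCS class 1-4.
#
# Solubility: the dose number D0 = M0 / (V0 * Cs), with M0 the highest single
# therapeutic dose (mg), V0 = 250 mL (a glass of water), and Cs the aqueous
# solubility (mg/mL). D0 <= 1 means the full dose dissolves in 250 mL: high
# solubility. Without a dose, the USP lower solubility bound (0.1 mg/mL)
# serves as the cutoff.
#
# Permeability: high/low by comparison against cutoffs anchored on the
# reference drug metoprolol: log P 1.72, log D at pH 7.4 -0.1954 (a model
# prediction for metoprolol), and Caco-2 log Papp -5.097 (Papp = 8.0e-6 cm/s,
# the threshold associated with >= 85% fraction absorbed).

#' Permeability and solubility cutoffs
#'
#' @param logP_cutoff,logD_cutoff,logPapp_cutoff permeability cutoffs per
#'   basis (metoprolol-anchored defaults 1.72 / -0.1954 / -5.097).
#' @param usp_solubility_cutoff solubility cutoff in mg/mL for the dose-free
#'   rule (default 0.1).
#' @param D0_boundary dose-number boundary (default 1).
#' @return object of class `bcs_cutoffs`.
#' @export
cutoff_set <- function(logP_cutoff = 1.72, logD_cutoff = -0.1954,
                       logPapp_cutoff = -5.097, usp_solubility_cutoff = 0.1,
                       D0_boundary = 1) {
  vals <- c(logP_cutoff, logD_cutoff, logPapp_cutoff, usp_solubility_cutoff,
            D0_boundary)
  if (!all(is.finite(vals))) {
    stop_bcstools("all cutoffs must be finite", "bcstools_non_positive_input_error")
  }
  structure(
    list(logP = logP_cutoff, logD = logD_cutoff, logPapp = logPapp_cutoff,
         usp_solubility = usp_solubility_cutoff, D0_boundary = D0_boundary),
    class = "bcs_cutoffs"
  )
}

#' @export
print.bcs_cutoffs <- function(x, ...) {
  cat(sprintf(
    "Cutoffs: logP >= %.4g, logD >= %.4g, logPapp >= %.4g -> high permeability;\n         Cs >= %.4g mg/mL (USP) or D0 <= %.4g -> high solubility\n",
    x$logP, x$logD, x$logPapp, x$usp_solubility, x$D0_boundary))
  invisible(x)
}

#' Dose context for the dose-number rule
#'
#' @param M0 highest single therapeutic dose, mg (> 0).
#' @param V0 reference gastric volume, mL (default 250).
#' @param MW molecular weight, g/mol (> 0); needed to convert log10 mol/L
#'   solubility to mg/mL. May be `NA` when the caller computes MW itself.
#' @return object of class `bcs_dose_context`.
#' @export
dose_context <- function(M0, V0 = 250, MW = NA_real_) {
  if (!is.finite(M0) || M0 <= 0 || !is.finite(V0) || V0 <= 0 ||
      (!is.na(MW) && MW <= 0)) {
    stop_bcstools("M0, V0 (and MW when given) must be > 0",
                  "bcstools_non_positive_input_error")
  }
  structure(list(M0 = M0, V0 = V0, MW = MW), class = "bcs_dose_context")
}

#' Convert log10 molar solubility to mg/mL
#'
#' `Cs = 10^logS * MW`: mol/L times g/mol gives g/L, which equals mg/mL.
#' The package convention for log S is log10 of mol/L throughout.
#'
#' @param logS log10 solubility in mol/L.
#' @param MW molecular weight, g/mol (> 0).
#' @return solubility in mg/mL (always > 0 and finite for finite input).
#' @export
logS_to_Cs <- function(logS, MW) {
  if (any(!is.finite(MW)) || any(MW <= 0)) {
    stop_bcstools("MW must be > 0", "bcstools_non_positive_input_error")
  }
  10^logS * MW
}

#' Dose number
#'
#' `D0 = M0 / (V0 * Cs)`: the ratio of the highest single dose to the drug
#' mass dissolvable in the reference volume. Strictly decreasing in `Cs`.
#'
#' @param M0 highest single dose, mg.
#' @param Cs solubility, mg/mL.
#' @param V0 reference volume, mL (default 250).
#' @return dimensionless dose number.
#' @export
dose_number <- function(M0, Cs, V0 = 250) {
  if (any(!is.finite(c(M0, Cs, V0))) || any(c(M0, Cs, V0) <= 0)) {
    stop_bcstools("M0, Cs and V0 must be finite and > 0",
                  "bcstools_non_positive_input_error")
  }
  M0 / (V0 * Cs)
}

#' Solubility class from the dose number
#'
#' High solubility iff `D0 <= boundary` (boundary value itself is high: a dose
#' that exactly dissolves in 250 mL counts as highly soluble).
#'
#' @param D0 dose number(s).
#' @param boundary class boundary (default 1).
#' @return character vector over `c("high","low")`.
#' @export
classify_solubility <- function(D0, boundary = 1) {
  stopifnot(all(is.finite(D0)))
  ifelse(D0 <= boundary, "high", "low")
}

#' Solubility class from the USP cutoff
#'
#' Dose-free alternative: high solubility iff `Cs >= cutoff` (0.1 mg/mL, the
#' lower limit of the USP "slightly soluble" range). The boundary value itself
#' classifies high.
#'
#' @param Cs solubility, mg/mL (> 0).
#' @param cutoff cutoff in mg/mL.
#' @return character vector over `c("high","low")`.
#' @export
classify_solubility_usp <- function(Cs, cutoff = 0.1) {
  if (any(!is.finite(Cs)) || any(Cs <= 0)) {
    stop_bcstools("Cs must be finite and > 0", "bcstools_non_positive_input_error")
  }
  ifelse(Cs >= cutoff, "high", "low")
}

#' Permeability class from a lipophilicity or permeability value
#'
#' Compares the value against the metoprolol-anchored cutoff for the chosen
#' basis. With the default boundary convention (`"ge"`) a value equal to the
#' cutoff classifies high — the reference drug defines the boundary and is a
#' (marginal) high-permeability drug. `boundary = "gt"` uses a strict
#' comparison, under which the boundary value classifies low; this is the
#' convention implied by the arithmetic of the published external-validation
#' table that [evaluate_table9()] reproduces.
#'
#' @param value numeric vector of predicted/measured values.
#' @param basis `"logP"`, `"logD"` or `"logPapp"`.
#' @param cutoffs a [cutoff_set()].
#' @param boundary `"ge"` (default) or `"gt"`.
#' @return character vector over `c("high","low")`.
#' @export
classify_permeability <- function(value, basis = c("logPapp", "logP", "logD"),
                                  cutoffs = cutoff_set(),
                                  boundary = c("ge", "gt")) {
  basis <- match.arg(basis)
  boundary <- match.arg(boundary)
  stopifnot(all(is.finite(value)), inherits(cutoffs, "bcs_cutoffs"))
  cut <- cutoffs[[basis]]
  high <- if (boundary == "ge") value >= cut else value > cut
  ifelse(high, "high", "low")
}

#' Correct log P for ionization: log D at a given pH
#'
#' For a singly ionizable substance, the distribution coefficient follows from
#' the partition coefficient and the Henderson-Hasselbalch ionized fraction:
#' acids `logD = logP - log10(1 + 10^(pH - pKa))`, bases
#' `logD = logP - log10(1 + 10^(pKa - pH))`. At `pH == pKa` the correction is
#' exactly `log10(2)`; far on the un-ionized side it vanishes and
#' `logD -> logP`. Always `logD <= logP`. Amphoteric/multiprotic species are
#' out of scope and rejected.
#'
#' @param logP partition coefficient (log10).
#' @param pKa acid dissociation constant (log10).
#' @param pH medium pH (default 7.4, the standard drug-development condition).
#' @param species `"acid"` or `"base"`.
#' @return log D value(s).
#' @export
logD_from_logP <- function(logP, pKa, pH = 7.4, species = c("acid", "base")) {
  species <- match.arg(species)
  stopifnot(all(is.finite(c(logP, pKa, pH))))
  x <- if (species == "acid") pH - pKa else pKa - pH
  logP - log10(1 + 10^x)
}

#' BCS class from the two attribute classes
#'
#' The 2x2 mapping: (high solubility, high permeability) -> 1,
#' (low, high) -> 2, (high, low) -> 3, (low, low) -> 4.
#'
#' @param solubility,permeability character vectors over `c("high","low")`.
#' @return integer vector of classes 1-4.
#' @export
assign_bcs <- function(solubility, permeability) {
  stopifnot(all(solubility %in% c("high", "low")),
            all(permeability %in% c("high", "low")),
            length(solubility) == length(permeability))
  s_low <- solubility == "low"
  p_low <- permeability == "low"
  as.integer(1L + s_low + 2L * p_low)
}

# solubility / permeability attribute implied by a BCS class
bcs_solubility_attribute <- function(class4) {
  ifelse(class4 %in% c(1L, 3L), "high", "low")
}
bcs_permeability_attribute <- function(class4) {
  ifelse(class4 %in% c(1L, 2L), "high", "low")
}

#' End-to-end provisional BCS prediction for one molecule
#'
#' Predicts the BCS-relevant properties with the supplied models, applies the
#' solubility rule (dose number when a dose is given, otherwise the USP cutoff
#' with a warning), classifies permeability on the configured basis, and
#' combines both into the BCS class.
#'
#' @param smiles a single SMILES string.
#' @param models named list mapping endpoints (`logS`, and at least the
#'   permeability basis in use) to either a trained `bcs_model_bundle` or a
#'   `function(smiles) -> numeric` (useful for plugging in external models).
#' @param dose optional [dose_context()]; when `NULL` the USP solubility rule
#'   is used and a `bcstools_missing_dose_warning` is raised.
#' @param cutoffs a [cutoff_set()].
#' @param perm_basis permeability basis (default `"logPapp"`, the most
#'   informative predictor; `"logP"` and `"logD"` remain selectable).
#' @param mw molecular weight override; by default MW is computed from the
#'   structure (or taken from `dose$MW` when set).
#' @param boundary permeability boundary convention, see
#'   [classify_permeability()].
#' @return object of class `bcs_result`: predicted `properties`, `MW`, `Cs`
#'   (mg/mL), `D0` (or `NA` without a dose), `solubility_class`,
#'   `permeability_class`, `permeability_basis` and `bcs_class`.
#' @export
predict_bcs <- function(smiles, models, dose = NULL, cutoffs = cutoff_set(),
                        perm_basis = c("logPapp", "logP", "logD"), mw = NULL,
                        boundary = "ge") {
  perm_basis <- match.arg(perm_basis)
  stopifnot(length(smiles) == 1L)
  canonical <- canonicalize_smiles(smiles)  # ParseError on invalid input
  need <- c("logS", perm_basis)
  missing_models <- setdiff(need, names(models))
  if (length(missing_models)) {
    stop_bcstools(paste("missing model(s):", paste(missing_models, collapse = ", ")),
                  "bcstools_missing_model_error")
  }
  run_model <- function(m) {
    if (inherits(m, "bcs_model_bundle")) as.numeric(predict(m, canonical))
    else if (is.function(m)) as.numeric(m(canonical))
    else stop_bcstools("models must be bundles or functions",
                       "bcstools_missing_model_error")
  }
  properties <- vapply(models, run_model, 0)

  MW <- if (!is.null(mw)) mw
        else if (!is.null(dose) && is.finite(dose$MW)) dose$MW
        else as.numeric(compute_descriptors(canonical, descriptor_set = "MW"))
  Cs <- logS_to_Cs(properties[["logS"]], MW)

  if (!is.null(dose)) {
    stopifnot(inherits(dose, "bcs_dose_context"))
    D0 <- dose_number(dose$M0, Cs, dose$V0)
    sol <- classify_solubility(D0, cutoffs$D0_boundary)
  } else {
    warn_bcstools("no dose given; falling back to the USP 0.1 mg/mL solubility rule",
                  "bcstools_missing_dose_warning")
    D0 <- NA_real_
    sol <- classify_solubility_usp(Cs, cutoffs$usp_solubility)
  }
  perm <- classify_permeability(properties[[perm_basis]], perm_basis, cutoffs,
                                boundary = boundary)
  structure(
    list(smiles = smiles, canonical_smiles = canonical,
         properties = properties, MW = MW, Cs = Cs, D0 = D0,
         solubility_class = sol, permeability_class = perm,
         permeability_basis = perm_basis,
         bcs_class = assign_bcs(sol, perm)),
    class = "bcs_result"
  )
}

#' @export
print.bcs_result <- function(x, ...) {
  cat(sprintf("BCS prediction for %s\n", x$canonical_smiles))
  for (p in names(x$properties)) {
    cat(sprintf("  %-8s %8.3f\n", p, x$properties[[p]]))
  }
  cat(sprintf("  MW %.2f g/mol, Cs %.4g mg/mL%s\n", x$MW, x$Cs,
              if (is.na(x$D0)) " (USP rule, no dose)" else sprintf(", D0 %.3g", x$D0)))
  cat(sprintf("  solubility %s, permeability %s (basis %s) -> BCS class %d\n",
              x$solubility_class, x$permeability_class, x$permeability_basis,
              x$bcs_class))
  invisible(x)
}

#' @export
format.bcs_result <- function(x, ...) {
  jsonlite::toJSON(
    list(smiles = x$smiles, canonical_smiles = x$canonical_smiles,
         properties = as.list(x$properties), MW = x$MW, Cs_mg_per_mL = x$Cs,
         D0 = if (is.na(x$D0)) NULL else x$D0,
         solubility_class = x$solubility_class,
         permeability_class = x$permeability_class,
         permeability_basis = x$permeability_basis,
         bcs_class = x$bcs_class),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
}
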
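# QSPR engine: stratified splitting, regression metrics, gradient-boosting
# training with a pluggable regressor registry, seeded random hyperparameter
# search, and k-fold cross-validation on the train+validation pool. The test
# partition is used exactly once, for the final generalization estimate; the
# tuning and CV routines physically never see its rows.

#' Construct a property dataset
#'
#' @param records data.frame with columns `canonical_smiles`, `label`, and
#'   optionally `name`.
#' @param endpoint one of `"logS"`, `"logP"`, `"logD"`, `"logPapp"`.
#' @param features optional list with `fingerprint` and `descriptors` matrices
#'   (rows aligned with `records`).
#' @param split optional factor/character vector over
#'   `c("train","valid","test")`.
#' @param split_seed seed used to create `split`, for provenance.
#' @return object of class `bcs_property_dataset`.
#' @export
property_dataset <- function(records, endpoint = c("logS", "logP", "logD", "logPapp"),
                             features = NULL, split = NULL, split_seed = NULL) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.data.frame(records),
            all(c("canonical_smiles", "label") %in% names(records)))
  if (!is.null(features)) {
    stopifnot(nrow(features$fingerprint) == nrow(records),
              nrow(features$descriptors) == nrow(records))
  }
  if (!is.null(split)) stopifnot(length(split) == nrow(records))
  structure(
    list(records = records, endpoint = endpoint, features = features,
         split = split, split_seed = split_seed),
    class = "bcs_property_dataset"
  )
}

#' @export
print.bcs_property_dataset <- function(x, ...) {
  cat(sprintf("Property dataset (%s): %d records", x$endpoint, nrow(x$records)))
  if (!is.null(x$split)) {
    tb <- table(factor(x$split, c("train", "valid", "test")))
    cat(sprintf("; split %d/%d/%d (seed %s)", tb[1L], tb[2L], tb[3L],
                format(x$split_seed)))
  }
  if (!is.null(x$features)) {
    cat(sprintf("; %d fp bits + %d descriptors", ncol(x$features$fingerprint),
                ncol(x$features$descriptors)))
  }
  cat("\n")
  invisible(x)
}

# Largest-remainder apportionment of `target` items over bins of given sizes.
apportion <- function(sizes, target) {
  if (target <= 0) return(integer(length(sizes)))
  ideal <- sizes * target / sum(sizes)
  base <- pmin(floor(ideal), sizes)
  rem <- target - sum(base)
  if (rem > 0) {
    room <- sizes - base
    pref <- order(-(ideal - base), seq_along(sizes))
    for (i in pref) {
      if (rem == 0) break
      if (room[i] > 0) { base[i] <- base[i] + 1L; rem <- rem - 1L }
    }
  }
  as.integer(base)
}

#' Label-stratified train/validation/test split
#'
#' Continuous labels are binned into `n_bins` quantile bins and each bin is
#' split at the requested ratios, so the three partitions share the label
#' distribution. Global partition sizes are enforced by largest-remainder
#' apportionment: they deviate from `round(n * ratio)` by at most one record.
#' The assignment is a pure function of the dataset, ratios, bins and seed.
#'
#' @param dataset a [property_dataset()] with at least 10 records.
#' @param ratios train/valid/test fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed integer RNG seed.
#' @param n_bins number of quantile bins for stratification (default 10).
#' @return the dataset with `$split` and `$split_seed` set.
#' @export
stratified_split <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 42L,
                             n_bins = 10L) {
  stopifnot(inherits(dataset, "bcs_property_dataset"))
  n <- nrow(dataset$records)
  if (n < 10L) stop_bcstools("dataset too small to split (need >= 10 records)",
                             "bcstools_too_small_error")
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  y <- dataset$records$label
  breaks <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE))
  bins <- if (length(breaks) <= 2L) rep(1L, n) else
    as.integer(cut(y, breaks = breaks, include.lowest = TRUE))
  bin_ids <- split(seq_len(n), bins)
  sizes <- lengths(bin_ids)

  n_train <- round(n * ratios[1L])
  n_valid <- round(n * ratios[2L])
  tr_alloc <- apportion(sizes, n_train)
  va_alloc <- apportion(sizes - tr_alloc, n_valid)

  assignment <- character(n)
  withr::with_seed(seed, {
    for (b in seq_along(bin_ids)) {
      idx <- sample(bin_ids[[b]])
      k1 <- tr_alloc[b]; k2 <- va_alloc[b]
      assignment[idx[seq_len(k1)]] <- "train"
      if (k2 > 0) assignment[idx[k1 + seq_len(k2)]] <- "valid"
      rest <- if (k1 + k2 == 0L) idx else idx[-seq_len(k1 + k2)]
      assignment[rest] <- "test"
    }
  })
  dataset$split <- factor(assignment, levels = c("train", "valid", "test"))
  dataset$split_seed <- as.integer(seed)
  dataset
}

#' Regression metrics
#'
#' Computes the coefficient of determination R^2 = 1 - SS_res/SS_tot, the mean
#' absolute error, and the root mean squared error.
#'
#' @param y_true,y_pred numeric vectors of equal nonzero length.
#' @return object of class `bcs_regression_metrics` with fields `r2`, `mae`,
#'   `rmse`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop_bcstools("y_true and y_pred must have equal nonzero length",
                  "bcstools_length_mismatch_error")
  }
  if (stats::var(y_true) == 0) {
    stop_bcstools("y_true has zero variance; R^2 is undefined",
                  "bcstools_degenerate_error")
  }
  e <- y_true - y_pred
  structure(
    list(
      r2 = 1 - sum(e^2) / sum((y_true - mean(y_true))^2),
      mae = mean(abs(e)),
      rmse = sqrt(mean(e^2)),
      n = length(y_true)
    ),
    class = "bcs_regression_metrics"
  )
}

#' @export
print.bcs_regression_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f, MAE = %.4f, RMSE = %.4f (n = %d)\n",
              x$r2, x$mae, x$rmse, x$n))
  invisible(x)
}

# ---------------------------------------------------------------------------
# regressor registry

.regressors <- new.env(parent = emptyenv())

#' Register a regression backend
#'
#' The engine is agnostic to the learning algorithm: any regressor obeying the
#' fit/predict/save/load contract can be registered and then addressed by name
#' in [train_regressor()], [tune_hyperparameters()] and [cross_validate()].
#' An xgboost-style gradient-boosting backend ships in-core;
#' [register_ranger_regressor()] adds a random-forest plug-in.
#'
#' @param name backend name.
#' @param fit `function(X, y, Xval, yval, params, seed)` returning a fitted
#'   model (`Xval`/`yval` may be `NULL`; backends may use them for early
#'   stopping).
#' @param predict `function(model, X)` returning numeric predictions.
#' @param save,load `function(model, path)` / `function(path)` for
#'   persistence; defaults use `saveRDS`/`readRDS`.
#' @param default_params named list of default hyperparameters (trial 1 of the
#'   hyperparameter search).
#' @param sample_params `function()` drawing one random hyperparameter
#'   configuration from the backend's search space (uses the current RNG
#'   state).
#' @return invisibly, `name`.
#' @export
register_regressor <- function(name, fit, predict, save = NULL, load = NULL,
                               default_params = list(), sample_params = NULL) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  if (is.null(save)) save <- function(model, path) saveRDS(model, path)
  if (is.null(load)) load <- function(path) readRDS(path)
  if (is.null(sample_params)) sample_params <- function() default_params
  assign(name, list(fit = fit, predict = predict, save = save, load = load,
                    default_params = default_params, sample_params = sample_params),
         envir = .regressors)
  invisible(name)
}

#' @rdname register_regressor
#' @export
list_regressors <- function() sort(ls(.regressors))

get_regressor <- function(name) {
  if (!exists(name, envir = .regressors, inherits = FALSE)) {
    stop_bcstools(sprintf("unknown regressor '%s'; see list_regressors()", name),
                  "bcstools_missing_model_error")
  }
  get(name, envir = .regressors, inherits = FALSE)
}

xgboost_defaults <- function() {
  list(eta = 0.05, max_depth = 6, min_child_weight = 1, subsample = 0.8,
       colsample_bytree = 0.8, lambda = 1, nrounds = 600,
       early_stopping_rounds = 50)
}

xgboost_fit <- function(X, y, Xval = NULL, yval = NULL, params = list(), seed = 42L) {
  p <- utils::modifyList(xgboost_defaults(), params)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  core <- list(objective = "reg:squarederror", eta = p$eta,
               max_depth = p$max_depth, min_child_weight = p$min_child_weight,
               subsample = p$subsample, colsample_bytree = p$colsample_bytree,
               lambda = p$lambda, nthread = 1L, seed = as.integer(seed))
  if (!is.null(Xval)) {
    dval <- xgboost::xgb.DMatrix(Xval, label = yval)
    xgboost::xgb.train(params = core, data = dtrain, nrounds = p$nrounds,
                       evals = list(valid = dval),
                       early_stopping_rounds = p$early_stopping_rounds,
                       verbose = 0)
  } else {
    xgboost::xgb.train(params = core, data = dtrain, nrounds = p$nrounds,
                       verbose = 0)
  }
}

xgboost_sample_params <- function() {
  list(
    eta = 10^stats::runif(1, -2, log10(0.3)),
    max_depth = sample(3:9, 1L),
    min_child_weight = sample(c(1, 3, 5, 10), 1L),
    subsample = stats::runif(1, 0.6, 1),
    colsample_bytree = stats::runif(1, 0.5, 1),
    lambda = 10^stats::runif(1, -2, 1),
    nrounds = 600,
    early_stopping_rounds = 50
  )
}

register_builtin_regressors <- function() {
  register_regressor(
    "xgboost",
    fit = xgboost_fit,
    predict = function(model, X) stats::predict(model, X),
    save = function(model, path) xgboost::xgb.save(model, path),
    load = function(path) xgboost::xgb.load(path),
    default_params = xgboost_defaults(),
    sample_params = xgboost_sample_params
  )
}

#' Register a random-forest plug-in backend
#'
#' Demonstrates the pluggable regressor contract with the `ranger` random
#' forest. Requires the `ranger` package.
#'
#' @return invisibly, the backend name `"ranger"`.
#' @export
register_ranger_regressor <- function() {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop_bcstools("the 'ranger' package is required for this backend",
                  "bcstools_missing_model_error")
  }
  register_regressor(
    "ranger",
    fit = function(X, y, Xval = NULL, yval = NULL, params = list(), seed = 42L) {
      p <- utils::modifyList(list(num.trees = 300, mtry = NULL, min.node.size = 5),
                             params)
      df <- data.frame(y = y, X)
      ranger::ranger(y ~ ., data = df, num.trees = p$num.trees,
                     mtry = p$mtry, min.node.size = p$min.node.size,
                     seed = seed, num.threads = 1L)
    },
    predict = function(model, X) {
      stats::predict(model, data.frame(X), num.threads = 1L)$predictions
    },
    default_params = list(num.trees = 300, min.node.size = 5),
    sample_params = function() list(
      num.trees = sample(c(200, 300, 500), 1L),
      min.node.size = sample(c(1, 5, 10), 1L)
    )
  )
}

.onLoad <- function(libname, pkgname) {
  register_builtin_regressors()
}

# ---------------------------------------------------------------------------
# training

dataset_matrix <- function(dataset, rows = NULL) {
  if (is.null(dataset$features)) {
    stop_bcstools("dataset has no features; run featurize_dataset() or clean_dataset()",
                  "bcstools_featurization_error")
  }
  X <- cbind(dataset$features$fingerprint, dataset$features$descriptors)
  colnames(X) <- c(paste0("fp", seq_len(ncol(dataset$features$fingerprint))),
                   colnames(dataset$features$descriptors))
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  X
}

#' Train a QSPR regressor
#'
#' Fits the named backend on the train partition (using the validation
#' partition for early stopping where the backend supports it) and evaluates
#' R^2/MAE/RMSE on all three partitions. The concatenation of the fingerprint
#' bits and the descriptor panel is the model input.
#'
#' @param dataset a featurized, split [property_dataset()].
#' @param algorithm registered backend name (default `"xgboost"`).
#' @param hyperparameters named list overriding the backend defaults.
#' @param seed integer seed passed to the backend.
#' @return object of class `bcs_model_bundle`: the fitted model plus endpoint,
#'   representation, algorithm, resolved hyperparameters, descriptor names,
#'   per-partition metrics, and an audit record of which partitions each stage
#'   touched.
#' @export
train_regressor <- function(dataset, algorithm = "xgboost",
                            hyperparameters = list(), seed = 42L) {
  stopifnot(inherits(dataset, "bcs_property_dataset"))
  if (is.null(dataset$split)) {
    stop_bcstools("dataset has no split; run stratified_split() first",
                  "bcstools_too_small_error")
  }
  backend <- get_regressor(algorithm)
  params <- utils::modifyList(backend$default_params, hyperparameters)
  X <- dataset_matrix(dataset)
  y <- dataset$records$label
  parts <- lapply(c(train = "train", valid = "valid", test = "test"),
                  function(p) which(dataset$split == p))
  if (stats::var(y[parts$train]) == 0) {
    stop_bcstools("training labels are constant", "bcstools_degenerate_error")
  }
  model <- withr::with_seed(seed, backend$fit(
    X[parts$train, , drop = FALSE], y[parts$train],
    X[parts$valid, , drop = FALSE], y[parts$valid],
    params, seed
  ))
  metrics <- lapply(parts, function(idx) {
    compute_metrics(y[idx], backend$predict(model, X[idx, , drop = FALSE]))
  })
  structure(
    list(
      endpoint = dataset$endpoint,
      representation = "fingerprint+descriptors",
      algorithm = algorithm,
      hyperparameters = params,
      descriptor_names = colnames(dataset$features$descriptors),
      fingerprint_bits = ncol(dataset$features$fingerprint),
      metrics = metrics,
      cv_summary = NULL,
      model = model,
      seed = as.integer(seed),
      audit = list(fit_partitions = c("train", "valid"),
                   test_used_for = "final metrics only")
    ),
    class = "bcs_model_bundle"
  )
}

#' @export
print.bcs_model_bundle <- function(x, ...) {
  cat(sprintf("QSPR model bundle: %s / %s (%s)\n", x$endpoint, x$algorithm,
              x$representation))
  for (p in names(x$metrics)) {
    m <- x$metrics[[p]]
    cat(sprintf("  %-5s R2 = %.3f, MAE = %.3f, RMSE = %.3f (n = %d)\n",
                p, m$r2, m$mae, m$rmse, m$n))
  }
  invisible(x)
}

#' Predict from a trained model bundle
#'
#' @param object a `bcs_model_bundle`.
#' @param newdata character vector of SMILES, or a feature matrix with the
#'   bundle's input layout.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.bcs_model_bundle <- function(object, newdata, ...) {
  backend <- get_regressor(object$algorithm)
  if (is.character(newdata)) {
    fp <- compute_ecfp(newdata, n_bits = object$fingerprint_bits)
    if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
    desc <- compute_descriptors(newdata, descriptor_set = object$descriptor_names)
    if (is.null(dim(desc))) desc <- matrix(desc, nrow = 1L,
                                           dimnames = list(NULL, names(desc)))
    newdata <- cbind(fp, desc)
    colnames(newdata) <- c(paste0("fp", seq_len(object$fingerprint_bits)),
                           object$descriptor_names)
  }
  backend$predict(object$model, newdata)
}

# ---------------------------------------------------------------------------
# hyperparameter search

#' Seeded random hyperparameter search
#'
#' Runs `n_evals` trials minimizing validation-partition RMSE. Trial 1 is
#' always the backend's default configuration, so the best result can never be
#' worse than the default. Remaining trials draw from the backend's documented
#' search space (or a user-supplied sampler). The search touches only the
#' train and validation partitions. The sequential model-based (TPE-style)
#' strategy of automated ML frameworks can be plugged in by passing a stateful
#' `search_space` function; random search is the in-core strategy.
#'
#' @param dataset featurized, split [property_dataset()] with a nonempty
#'   validation partition.
#' @param algorithm registered backend name.
#' @param search_space optional `function()` returning one hyperparameter
#'   configuration per call.
#' @param n_evals number of trials (default 50).
#' @param seed RNG seed controlling the whole search.
#' @return list with `best_params`, `best_rmse`, and `trials` (a data.frame
#'   log with one row per trial: parameters as JSON, validation RMSE, status).
#' @export
tune_hyperparameters <- function(dataset, algorithm = "xgboost",
                                 search_space = NULL, n_evals = 50L, seed = 42L) {
  stopifnot(inherits(dataset, "bcs_property_dataset"), n_evals >= 1L)
  if (is.null(dataset$split) || !any(dataset$split == "valid")) {
    stop_bcstools("a nonempty validation partition is required for tuning",
                  "bcstools_too_small_error")
  }
  backend <- get_regressor(algorithm)
  sampler <- if (is.null(search_space)) backend$sample_params else search_space
  X <- dataset_matrix(dataset)
  y <- dataset$records$label
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "valid")

  configs <- withr::with_seed(seed, {
    c(list(backend$default_params),
      if (n_evals > 1L) lapply(seq_len(n_evals - 1L), function(i) sampler()))
  })
  rmse <- rep(NA_real_, n_evals)
  status <- rep("ok", n_evals)
  for (i in seq_len(n_evals)) {
    fitted <- tryCatch(
      withr::with_seed(seed + i, backend$fit(
        X[tr, , drop = FALSE], y[tr], X[va, , drop = FALSE], y[va],
        utils::modifyList(backend$default_params, configs[[i]]), seed
      )),
      error = function(e) e
    )
    if (inherits(fitted, "error")) {
      status[i] <- paste("failed:", conditionMessage(fitted))
      next
    }
    rmse[i] <- sqrt(mean((y[va] - backend$predict(fitted, X[va, , drop = FALSE]))^2))
  }
  best <- which.min(rmse)
  list(
    best_params = utils::modifyList(backend$default_params, configs[[best]]),
    best_rmse = rmse[best],
    trials = data.frame(
      trial = seq_len(n_evals),
      params = vapply(configs, function(p)
        as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA)), ""),
      valid_rmse = rmse,
      status = status,
      stringsAsFactors = FALSE
    )
  )
}

# ---------------------------------------------------------------------------
# cross-validation

#' k-fold cross-validation on the train+validation pool
#'
#' After tuning, the train and validation partitions are pooled and the model
#' is re-fit k times, each fold held out once; the test partition is never
#' touched. Reports mean and standard deviation of each metric over folds for
#' both the fold-train and held-out sides, plus a "mean (sd)" formatted table.
#'
#' @param dataset featurized, split [property_dataset()].
#' @param algorithm registered backend name.
#' @param hyperparameters named list (e.g. `best_params` from tuning).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment and fits.
#' @return list with `summary` (data.frame: partition, metric, mean, sd,
#'   formatted) and `fold_metrics`.
#' @export
cross_validate <- function(dataset, algorithm = "xgboost",
                           hyperparameters = list(), k = 5L, seed = 42L) {
  stopifnot(inherits(dataset, "bcs_property_dataset"), k >= 2L)
  if (is.null(dataset$split)) {
    stop_bcstools("dataset has no split; run stratified_split() first",
                  "bcstools_too_small_error")
  }
  backend <- get_regressor(algorithm)
  params <- utils::modifyList(backend$default_params, hyperparameters)
  pool <- which(dataset$split %in% c("train", "valid"))
  if (floor(length(pool) / k) < 2L) {
    stop_bcstools("each fold must contain at least 2 records",
                  "bcstools_too_small_error")
  }
  X <- dataset_matrix(dataset)
  y <- dataset$records$label
  fold_of <- withr::with_seed(seed, {
    sample(rep_len(seq_len(k), length(pool)))
  })
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- pool[fold_of == f]
    fit_idx <- pool[fold_of != f]
    model <- withr::with_seed(seed + f, backend$fit(
      X[fit_idx, , drop = FALSE], y[fit_idx], NULL, NULL, params, seed + f
    ))
    fold_metrics[[f]] <- list(
      train = compute_metrics(y[fit_idx],
                              backend$predict(model, X[fit_idx, , drop = FALSE])),
      valid = compute_metrics(y[hold],
                              backend$predict(model, X[hold, , drop = FALSE]))
    )
  }
  rows <- list()
  for (part in c("train", "valid")) {
    for (metric in c("rmse", "mae", "r2")) {
      vals <- vapply(fold_metrics, function(m) m[[part]][[metric]], 0)
      rows[[length(rows) + 1L]] <- data.frame(
        partition = part, metric = metric, mean = mean(vals), sd = stats::sd(vals),
        formatted = sprintf("%.3f(%.3f)", mean(vals), stats::sd(vals)),
        stringsAsFactors = FALSE
      )
    }
  }
  list(summary = do.call(rbind, rows), fold_metrics = fold_metrics, k = k,
       seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# persistence

#' Save / load a model bundle
#'
#' A bundle directory holds a JSON manifest (endpoint, representation,
#' algorithm, hyperparameters, descriptor names, metrics) plus the backend's
#' native model file, making trained models self-describing. Reloading gives
#' bit-identical predictions.
#'
#' @param bundle a `bcs_model_bundle`.
#' @param dir target directory (created if needed).
#' @return `save_model_bundle()`: invisibly, `dir`. `load_model_bundle()`: the
#'   restored bundle.
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "bcs_model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  backend <- get_regressor(bundle$algorithm)
  manifest <- bundle[c("endpoint", "representation", "algorithm",
                       "hyperparameters", "descriptor_names",
                       "fingerprint_bits", "seed", "audit")]
  manifest$metrics <- lapply(bundle$metrics, unclass)
  if (!is.null(bundle$cv_summary)) manifest$cv_summary <- bundle$cv_summary
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  backend$save(bundle$model, file.path(dir, "model.bin"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  backend <- get_regressor(manifest$algorithm)
  bundle <- list(
    endpoint = manifest$endpoint,
    representation = manifest$representation,
    algorithm = manifest$algorithm,
    hyperparameters = as.list(manifest$hyperparameters),
    descriptor_names = manifest$descriptor_names,
    fingerprint_bits = manifest$fingerprint_bits,
    metrics = lapply(manifest$metrics, function(m)
      structure(as.list(m), class = "bcs_regression_metrics")),
    cv_summary = manifest$cv_summary,
    model = backend$load(file.path(dir, "model.bin")),
    seed = manifest$seed,
    audit = manifest$audit
  )
  structure(bundle, class = "bcs_model_bundle")
}

#' Export per-partition metrics as a table
#'
#' One row per partition with RMSE/MAE/R^2 columns, matching the layout used
#' in QSPR benchmarking reports.
#'
#' @param bundle a `bcs_model_bundle`.
#' @param path optional CSV output path.
#' @return data.frame (invisibly written to `path` when given).
#' @export
metrics_table <- function(bundle, path = NULL) {
  df <- do.call(rbind, lapply(names(bundle$metrics), function(p) {
    m <- bundle$metrics[[p]]
    data.frame(endpoint = bundle$endpoint, algorithm = bundle$algorithm,
               partition = p, rmse = m$rmse, mae = m$mae, r2 = m$r2, n = m$n,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
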
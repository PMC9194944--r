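#' @name pipeline
#' @title End-to-end training, prediction and cross-validation
#'
#' @description
#' The full pipeline is: energy-profile encoding, wavelet +
#' pseudo-positional feature extraction, z-score standardization, SVM-RFE
#' with correlation bias reduction, and the two-layer stacking classifier.
#' [rp_train()] fits everything on labelled records and returns a single
#' model artifact carrying all configuration needed to score new
#' sequences; [crossvalidate()] refits the entire pipeline inside every
#' fold so feature selection never sees validation data.
NULL

#' Pipeline configuration
#'
#' @param wavelet a [wavelet_spec()].
#' @param lambda pseudo-positional maximum lag (default 5).
#' @param dct_k leading DCT coefficients per level (default 5).
#' @param dct_mode see [extract_dwt_features()].
#' @param selection a [selection_config()].
#' @param stacking a [base_layer_spec()].
#' @param folds out-of-fold count for the stacking meta-features.
#' @param tune run the base-layer grid search before fitting.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(wavelet = wavelet_spec(), lambda = 5L,
                            dct_k = 5L, dct_mode = "dct",
                            selection = selection_config(),
                            stacking = base_layer_spec(),
                            folds = 5L, tune = FALSE) {
  structure(list(wavelet = wavelet, lambda = as.integer(lambda),
                 dct_k = as.integer(dct_k), dct_mode = dct_mode,
                 selection = selection, stacking = stacking,
                 folds = as.integer(folds), tune = isTRUE(tune)),
            class = "pipeline_config")
}

extraction_config <- function(config) {
  list(family = config$wavelet$family, levels = config$wavelet$levels,
       boundary = config$wavelet$boundary, lambda = config$lambda,
       dct_k = config$dct_k, dct_mode = config$dct_mode)
}

pipeline_features <- function(records, config) {
  extract_features(records, spec = config$wavelet, lambda = config$lambda,
                   dct_k = config$dct_k, dct_mode = config$dct_mode)
}

# core fit on an already-extracted feature matrix
fit_pipeline_on_features <- function(X, y, config, seed) {
  std <- standardize(X)
  ranking <- rfe_rank(std$X, y, config$selection)
  k <- min(config$selection$k, ncol(X))
  selected <- select_top_k(ranking, k)
  Xsel <- std$X[, selected, drop = FALSE]
  spec <- config$stacking
  if (config$tune) spec <- tune_base(Xsel, y, spec, seed = seed)
  stack <- stacking_fit(Xsel, y, spec, folds = config$folds, seed = seed)
  list(standardizer = std$params, ranking = ranking, selected = selected,
       stack = stack)
}

#' Train the full pipeline
#'
#' @param records labelled `protein_record` list; alternatively pass a
#'   pre-extracted feature matrix as `features` with `labels`.
#' @param config a [pipeline_config()].
#' @param seed RNG seed (fold assignment, stochastic members).
#' @param features,labels optional pre-extracted feature matrix (from
#'   [extract_features()] with the same configuration) and its 0/1 labels.
#' @return An `rp_model` bundling extraction config, standardization
#'   parameters, the feature ranking and selected subset, and the fitted
#'   stacking classifier.
#' @export
rp_train <- function(records = NULL, config = pipeline_config(), seed = 1L,
                     features = NULL, labels = NULL) {
  if (is.null(features)) {
    if (is.null(records)) stop("supply 'records' or 'features' + 'labels'")
    features <- pipeline_features(records, config)
    labels <- record_labels(records)
  }
  if (is.null(labels)) stop("'labels' is required with 'features'")
  if (anyNA(labels)) stop("all training records must be labelled")
  fit <- fit_pipeline_on_features(features, as.integer(labels), config, seed)
  structure(list(extraction = extraction_config(config),
                 feature_names = colnames(features),
                 standardizer = fit$standardizer,
                 ranking = fit$ranking,
                 selected = fit$selected,
                 stack = fit$stack,
                 config = config,
                 seed = seed),
            class = "rp_model")
}

#' @export
print.rp_model <- function(x, ...) {
  cat("<rp_model> stacked R-protein classifier\n",
      " features: ", length(x$feature_names), " extracted, ",
      length(x$selected), " selected\n",
      " wavelet: ", x$extraction$family, ", ", x$extraction$levels,
      " levels; lambda = ", x$extraction$lambda, "\n", sep = "")
  invisible(x)
}

check_extraction_match <- function(model, config_attr) {
  stored <- model$extraction
  for (key in names(stored)) {
    if (!identical(as.character(stored[[key]]),
                   as.character(config_attr[[key]])))
      stop("feature configuration mismatch: model was trained with ", key,
           " = ", stored[[key]], " but features were extracted with ", key,
           " = ", config_attr[[key]])
  }
}

#' Score new sequences with a trained pipeline
#'
#' @param model an `rp_model` from [rp_train()].
#' @param records `protein_record` list (features are extracted with the
#'   model's stored configuration); alternatively a raw feature matrix
#'   whose `config` attribute, if present, must match the model's.
#' @return Data frame with `id`, `probability` and `label` (threshold 0.5).
#' @export
rp_predict <- function(model, records) {
  stopifnot(inherits(model, "rp_model"))
  if (is.matrix(records)) {
    X <- records
    cfg <- attr(X, "config")
    if (!is.null(cfg)) check_extraction_match(model, cfg)
    ids <- rownames(X)
  } else {
    if (inherits(records, "protein_record")) records <- list(records)
    cfg <- model$extraction
    X <- extract_features(records,
                          spec = wavelet_spec(cfg$family, cfg$levels,
                                              cfg$boundary),
                          lambda = cfg$lambda, dct_k = cfg$dct_k,
                          dct_mode = cfg$dct_mode)
    ids <- rownames(X)
  }
  if (ncol(X) != length(model$feature_names))
    stop("feature width ", ncol(X), " does not match the model's expected ",
         length(model$feature_names))
  Xs <- apply_standardizer(model$standardizer, X)
  p <- predict_proba(model$stack, Xs[, model$selected, drop = FALSE])
  data.frame(id = if (is.null(ids)) seq_along(p) else ids,
             probability = p,
             label = as.integer(p >= 0.5))
}

#' @export
predict_proba.rp_model <- function(model, X) {
  rp_predict(model, X)$probability
}

#' Nested stratified k-fold cross-validation
#'
#' Feature extraction is sequence-only (label-free) and is computed once;
#' everything label-dependent — standardization, feature ranking and
#' selection, optional tuning and the stacking fit — is refit inside each
#' training fold. Setting `selection_inside = FALSE` deliberately performs
#' selection on all data first (a leakage demonstration, not a protocol to
#' use).
#'
#' @param records labelled `protein_record` list.
#' @param config a [pipeline_config()].
#' @param k number of folds (default 5).
#' @param seed RNG seed for fold assignment and member fits.
#' @param selection_inside keep feature selection inside the folds
#'   (default `TRUE`).
#' @return An `evaluation_report`: list with `metrics` (averaged over
#'   folds), `auc` (pooled over out-of-fold scores), `per_fold`, `roc`
#'   curve points, `scores` and `folds`.
#' @export
crossvalidate <- function(records, config = pipeline_config(), k = 5L,
                          seed = 1L, selection_inside = TRUE) {
  y <- record_labels(records)
  if (anyNA(y)) stop("all records must be labelled")
  X <- pipeline_features(records, config)
  folds_id <- make_folds(y, k, seed)
  scores <- numeric(length(y))
  per_fold <- vector("list", k)
  outside <- NULL
  if (!selection_inside)
    outside <- fit_pipeline_on_features(X, y, config, seed)
  for (f in seq_len(k)) {
    tr <- folds_id != f
    if (selection_inside) {
      fit <- fit_pipeline_on_features(X[tr, , drop = FALSE], y[tr],
                                      config, seed)
    } else {
      # leakage variant: reuse selection fitted on all data, refit the stack
      Xsel <- apply_standardizer(outside$standardizer,
                                 X[tr, , drop = FALSE])[, outside$selected,
                                                        drop = FALSE]
      stack <- stacking_fit(Xsel, y[tr], config$stacking,
                            folds = config$folds, seed = seed)
      fit <- list(standardizer = outside$standardizer,
                  selected = outside$selected, stack = stack)
    }
    Xte <- apply_standardizer(fit$standardizer,
                              X[!tr, , drop = FALSE])[, fit$selected,
                                                      drop = FALSE]
    p <- predict_proba(fit$stack, Xte)
    scores[!tr] <- p
    m <- compute_metrics(confusion_counts(y[!tr], as.integer(p >= 0.5)))
    per_fold[[f]] <- c(m, auc = roc_auc(p, y[!tr])$auc)
  }
  fold_mat <- do.call(rbind, per_fold)
  pooled <- roc_auc(scores, y)
  structure(list(metrics = colMeans(fold_mat, na.rm = TRUE),
                 auc = pooled$auc,
                 per_fold = fold_mat,
                 roc = pooled$curve,
                 scores = scores,
                 folds = folds_id,
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", nrow(x$per_fold), "-fold cross-validation\n",
      sep = "")
  m <- x$metrics
  for (nm in names(m))
    cat(sprintf("  %-12s %.4f\n", nm, m[[nm]]))
  cat(sprintf("  %-12s %.4f (pooled)\n", "auc", x$auc))
  invisible(x)
}

#' Write an evaluation report as JSON (+ optional ROC TSV)
#'
#' @param report an `evaluation_report`.
#' @param path JSON output path.
#' @param roc_path optional TSV path for the pooled ROC points.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, roc_path = NULL) {
  out <- list(metrics = as.list(report$metrics),
              auc_pooled = report$auc,
              per_fold = as.data.frame(report$per_fold))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(roc_path))
    write.table(report$roc, roc_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
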
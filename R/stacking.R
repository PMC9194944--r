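#' @name stacking
#' @title Two-layer stacking classifier
#'
#' @description
#' Six base classifiers — k-nearest neighbours, a classic gradient-boosted
#' decision tree, an RBF-kernel SVM, a regularised extreme-gradient-boosted
#' tree, a histogram/leaf-wise boosted tree, and a random forest — are
#' combined by an SVM meta-classifier. The meta-classifier is trained on
#' out-of-fold positive-class probabilities (an n x 6 matrix), so no base
#' model ever scores a sample it was trained on; the base models are then
#' refit on all training data for prediction.
#'
#' The three boosted-tree members are all fit through the xgboost engine
#' with member-specific growth policies: `gbdt` uses depth-wise shallow
#' trees with a small learning rate (classic gradient boosting defaults),
#' `xgb` uses the engine's regularised defaults, and `lgb` uses
#' histogram-based leaf-wise growth with a 31-leaf cap (the leaf-wise
#' strategy popularised by LightGBM).
NULL

MEMBER_NAMES <- c("knn", "gbdt", "svm", "xgb", "lgb", "rf")

default_member_params <- function() {
  list(
    knn  = list(k = 5L),
    gbdt = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
    svm  = list(cost = 1, gamma = NULL),  # gamma NULL -> 1/d
    xgb  = list(nrounds = 100L, max_depth = 6L, eta = 0.3),
    lgb  = list(nrounds = 100L, eta = 0.1, max_leaves = 31L),
    rf   = list(ntree = 500L)
  )
}

#' Base-layer specification
#'
#' The six members with their hyperparameters and tuning grids. The
#' shipped `"fast"` grid is a small, documented coarsening suitable for
#' desk-scale runs; `"paper"` is the full published search range
#' (tree counts 100..1000 step 25; SVM `C = 2^{-5..15}` step `2^2` and
#' `gamma = 2^{-15..15}` step `2^1` on the exponent; leaf-wise depth 1..25
#' and learning rate 0.1..0.8 step 0.01).
#'
#' @param grid `"fast"` (default) or `"paper"`.
#' @param params optional list overriding per-member default
#'   hyperparameters.
#' @return A `base_layer_spec` list.
#' @export
base_layer_spec <- function(grid = c("fast", "paper"), params = NULL) {
  grid <- match.arg(grid)
  p <- default_member_params()
  if (!is.null(params)) {
    for (m in names(params)) {
      if (!m %in% MEMBER_NAMES) stop("unknown base member: ", m)
      p[[m]][names(params[[m]])] <- params[[m]]
    }
  }
  grids <- if (grid == "fast") {
    list(
      knn  = expand.grid(k = c(3L, 5L, 7L)),
      gbdt = expand.grid(nrounds = c(50L, 100L, 200L)),
      svm  = expand.grid(cost = 2^c(-1, 1, 3, 5), gamma = 2^c(-9, -5, -3)),
      xgb  = expand.grid(nrounds = c(50L, 100L, 200L)),
      lgb  = expand.grid(nrounds = c(50L, 100L), eta = c(0.1, 0.3)),
      rf   = expand.grid(ntree = c(200L, 500L))
    )
  } else {
    list(
      knn  = expand.grid(k = 5L),
      gbdt = expand.grid(nrounds = 100L),
      svm  = expand.grid(cost = 2^seq(-5, 15, by = 2),
                         gamma = 2^seq(-15, 15, by = 1)),
      xgb  = expand.grid(nrounds = seq(100L, 1000L, by = 25L)),
      lgb  = expand.grid(nrounds = seq(100L, 1000L, by = 25L),
                         max_depth = seq(1L, 25L, by = 1L),
                         eta = seq(0.1, 0.8, by = 0.01)),
      rf   = expand.grid(ntree = seq(100L, 1000L, by = 25L))
    )
  }
  structure(list(members = MEMBER_NAMES, params = p, grids = grids,
                 grid = grid),
            class = "base_layer_spec")
}

xgb_train <- function(X, y, nrounds, params, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", nthread = 1L,
                    seed = seed), params),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

fit_member <- function(name, X, y, params, seed) {
  fit <- switch(name,
    knn = list(train = X, cl = factor(y, levels = c(0L, 1L)), k = params$k),
    gbdt = xgb_train(X, y, params$nrounds,
                     list(max_depth = params$max_depth, eta = params$eta),
                     seed),
    svm = {
      g <- if (is.null(params$gamma)) 1 / ncol(X) else params$gamma
      set.seed(seed)
      e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                 type = "C-classification", kernel = "radial",
                 cost = params$cost, gamma = g, scale = FALSE,
                 probability = TRUE)
    },
    xgb = xgb_train(X, y, params$nrounds,
                    list(max_depth = params$max_depth, eta = params$eta),
                    seed),
    lgb = xgb_train(X, y, params$nrounds,
                    list(eta = params$eta, tree_method = "hist",
                         grow_policy = "lossguide", max_depth = 0L,
                         max_leaves = params$max_leaves),
                    seed),
    rf = {
      set.seed(seed)
      randomForest::randomForest(x = X, y = factor(y, levels = c(0L, 1L)),
                                 ntree = params$ntree)
    },
    stop("unknown base member: ", name))
  list(name = name, fit = fit)
}

predict_member <- function(member, X) {
  p <- switch(member$name,
    knn = {
      pr <- class::knn(member$fit$train, X, member$fit$cl,
                       k = member$fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    svm = {
      pred <- predict(member$fit, X, probability = TRUE)
      attr(pred, "probabilities")[, "1"]
    },
    rf = predict(member$fit, X, type = "prob")[, "1"],
    # the three boosted-tree members share the xgboost engine
    predict(member$fit, xgboost::xgb.DMatrix(X)))
  as.numeric(p)
}

# stratified fold assignment, reproducible per seed
make_folds <- function(y, k, seed) {
  if (k < 2L) stop("'folds' must be >= 2")
  tab <- table(y)
  if (any(tab < k))
    stop("every class needs at least as many members as folds (k = ", k, ")")
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# accuracy of k-fold CV at one grid point, used by the grid search
member_cv_accuracy <- function(name, X, y, params, folds_id, seed) {
  correct <- 0L
  for (f in sort(unique(folds_id))) {
    tr <- folds_id != f
    member <- fit_member(name, X[tr, , drop = FALSE], y[tr], params, seed)
    p <- predict_member(member, X[!tr, , drop = FALSE])
    correct <- correct + sum((p >= 0.5) == (y[!tr] == 1L))
  }
  correct / length(y)
}

#' Grid-search tuning of the base layer
#'
#' Per-member grid search scored by inner stratified cross-validated
#' accuracy; ties keep the first grid point, so results are deterministic
#' for a fixed seed.
#'
#' @param X feature matrix.
#' @param y binary labels (0/1).
#' @param spec a [base_layer_spec()].
#' @param folds inner CV folds (default 3).
#' @param seed RNG seed.
#' @return The spec with `params` replaced by the selected grid points.
#' @export
tune_base <- function(X, y, spec = base_layer_spec(), folds = 3L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("tuning needs both classes present")
  folds_id <- make_folds(y, folds, seed)
  for (name in spec$members) {
    grid <- spec$grids[[name]]
    if (nrow(grid) <= 1L) {
      if (nrow(grid) == 1L)
        spec$params[[name]][names(grid)] <- as.list(grid[1L, , drop = FALSE])
      next
    }
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      params <- spec$params[[name]]
      params[names(grid)] <- as.list(grid[i, , drop = FALSE])
      member_cv_accuracy(name, X, y, params, folds_id, seed)
    }, 0.0)
    best <- which.max(acc)  # first maximum on ties
    spec$params[[name]][names(grid)] <- as.list(grid[best, , drop = FALSE])
  }
  spec
}

#' Fit the two-layer stacking classifier
#'
#' Builds the n x 6 out-of-fold meta-feature matrix (one positive-class
#' probability column per base member), refits every base member on the
#' full data, and fits the SVM meta-classifier on the meta-features.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y binary labels (0/1), both classes present in every fold.
#' @param spec a [base_layer_spec()].
#' @param folds out-of-fold count for meta-feature generation (default 5).
#' @param seed RNG seed controlling fold assignment and stochastic members.
#' @return A `stacking_model` with fitted members, meta-classifier, fold
#'   assignment and the out-of-fold meta-feature matrix.
#' @export
stacking_fit <- function(X, y, spec = base_layer_spec(), folds = 5L,
                         seed = 1L) {
  stopifnot(is.matrix(X))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("stacking needs both classes present")
  folds_id <- make_folds(y, folds, seed)
  n <- nrow(X)
  meta <- matrix(NA_real_, n, length(spec$members),
                 dimnames = list(NULL, spec$members))
  for (f in sort(unique(folds_id))) {
    tr <- folds_id != f
    for (name in spec$members) {
      member <- fit_member(name, X[tr, , drop = FALSE], y[tr],
                           spec$params[[name]], seed)
      meta[!tr, name] <- predict_member(member, X[!tr, , drop = FALSE])
    }
  }
  members <- lapply(spec$members, function(name)
    fit_member(name, X, y, spec$params[[name]], seed))
  names(members) <- spec$members
  set.seed(seed)
  meta_fit <- e1071::svm(x = meta, y = factor(y, levels = c(0L, 1L)),
                         type = "C-classification", kernel = "radial",
                         scale = FALSE, probability = TRUE)
  structure(list(members = members, meta = meta_fit, spec = spec,
                 folds = folds_id, oof_meta = meta, seed = seed,
                 n_features = ncol(X)),
            class = "stacking_model")
}

#' Positive-class probabilities from a stacking model
#'
#' @param model a `stacking_model` (or a full pipeline `rp_model`, which
#'   applies its stored feature transforms first).
#' @param X feature matrix in the model's training feature space.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, X) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.stacking_model <- function(model, X) {
  stopifnot(is.matrix(X))
  if (ncol(X) != model$n_features)
    stop("feature width ", ncol(X), " does not match the model's expected ",
         model$n_features)
  meta <- do.call(cbind, lapply(model$members, predict_member, X))
  colnames(meta) <- names(model$members)
  pred <- predict(model$meta, meta, probability = TRUE)
  as.numeric(attr(pred, "probabilities")[, "1"])
}

#' @export
predict.stacking_model <- function(object, newdata, ...) {
  as.integer(predict_proba(object, newdata) >= 0.5)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a fitted model
#'
#' Serialises a `stacking_model` or full pipeline `rp_model` together with
#' a format version; loading a file with a different version (or something
#' that is not a saved model) is an explicit error.
#'
#' @param model the fitted model.
#' @param path file path.
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("stacking_model", "rp_model")))
    stop("'model' must be a stacking_model or rp_model")
  saveRDS(list(format_version = MODEL_FORMAT_VERSION,
               package_version = as.character(utils::packageVersion("stackrp")),
               model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (!is.list(obj) || is.null(obj$format_version) || is.null(obj$model))
    stop("file ", path, " is not a saved model")
  if (obj$format_version != MODEL_FORMAT_VERSION)
    stop("model format version ", obj$format_version,
         " does not match supported version ", MODEL_FORMAT_VERSION)
  obj$model
}
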
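#' @name feature_selection
#' @title SVM-RFE feature ranking with correlation bias reduction
#'
#' @description
#' Features are ranked by recursive feature elimination driven by a kernel
#' SVM: at each round an SVM is trained on the surviving features, every
#' surviving feature is scored by the change in the dual objective when it
#' is removed from the kernel (dual variables held fixed), and the
#' worst-scoring block is eliminated. While more features survive than the
#' schedule threshold, half are eliminated per round; after that, one per
#' round. Correlation bias reduction (CBR) groups surviving features whose
#' absolute Pearson correlation reaches `rth` (single linkage) and replaces
#' every group member's score with the group maximum, so a group of
#' near-duplicate informative features is not picked off one by one.
NULL

#' Selection configuration
#'
#' Defaults follow the reference parameterisation of the SVM-RFE+CBR
#' method: RBF kernel, `cost = 16`, `gamma = 0.0078`, CBR enabled with
#' correlation threshold 0.9, retained subset size `k = 112`.
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width.
#' @param use_cbr apply the correlation bias reduction correction.
#' @param rth absolute-correlation threshold for CBR grouping, in (0, 1].
#' @param k retained subset size (default 112).
#' @param schedule_threshold eliminate half the survivors per round while
#'   more than this many remain, then one per round; default `4 * k`.
#' @param seed stored for provenance (the procedure itself is
#'   deterministic).
#' @return A `selection_config` list.
#' @export
selection_config <- function(kernel = c("rbf", "linear"), cost = 16,
                             gamma = 0.0078, use_cbr = TRUE, rth = 0.9,
                             k = 112L, schedule_threshold = 4L * k,
                             seed = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, gamma > 0, rth > 0, rth <= 1, k >= 1)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 use_cbr = isTRUE(use_cbr), rth = rth, k = as.integer(k),
                 schedule_threshold = as.integer(schedule_threshold),
                 seed = seed),
            class = "selection_config")
}

#' Z-score standardization with reusable parameters
#'
#' Centers every column to mean 0 and scales to unit (sample) variance.
#' Zero-variance columns are mapped to 0 with a warning. The returned
#' parameters can be re-applied to new data at prediction time.
#'
#' @param X numeric feature matrix with at least 2 rows.
#' @return List with `X` (standardized matrix), `center` and `scale`
#'   vectors; class `standardizer` is carried on the parameter list.
#' @export
standardize <- function(X) {
  if (!is.matrix(X) || nrow(X) < 2L)
    stop("standardization needs a matrix with at least 2 samples")
  center <- colMeans(X)
  scale_ <- apply(X, 2L, sd)
  zero <- !is.finite(scale_) | scale_ == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature column(s) mapped to 0")
    scale_[zero] <- 1
  }
  params <- structure(list(center = center, scale = scale_),
                      class = "standardizer")
  list(X = apply_standardizer(params, X), center = center, scale = scale_,
       params = params)
}

#' @rdname standardize
#' @param params a `standardizer` parameter list from a previous fit.
#' @export
apply_standardizer <- function(params, X) {
  stopifnot(inherits(params, "standardizer"))
  if (ncol(X) != length(params$center))
    stop("feature width ", ncol(X), " does not match the stored ",
         length(params$center), " standardization parameters")
  sweep(sweep(X, 2L, params$center), 2L, params$scale, "/")
}

#' Correlation bias reduction correction
#'
#' Groups features by absolute Pearson correlation `>= rth` (single
#' linkage over the supplied columns) and replaces each member's criterion
#' by its group's maximum; singleton groups are unchanged.
#'
#' @param criteria numeric scores aligned with the columns of `features`.
#' @param features matrix of the surviving feature columns.
#' @param rth absolute-correlation threshold in (0, 1].
#' @return Corrected criterion vector.
#' @export
cbr_correct <- function(criteria, features, rth) {
  d <- ncol(features)
  stopifnot(length(criteria) == d, rth > 0, rth <= 1)
  if (d < 2L) return(criteria)
  cm <- suppressWarnings(abs(cor(features)))
  cm[!is.finite(cm)] <- 0
  adj <- cm >= rth
  diag(adj) <- FALSE
  if (!any(adj)) return(criteria)
  # connected components by breadth-first search over the adjacency matrix
  comp <- integer(d)
  cur <- 0L
  for (v in seq_len(d)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue) > 0L) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  out <- criteria
  for (g in unique(comp)) {
    idx <- which(comp == g)
    if (length(idx) > 1L) out[idx] <- max(criteria[idx])
  }
  out
}

# per-feature elimination criterion for the current SVM fit
svm_rfe_criteria <- function(X, y, config) {
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                    type = "C-classification",
                    kernel = if (config$kernel == "rbf") "radial" else "linear",
                    cost = config$cost, gamma = config$gamma,
                    scale = FALSE)
  sv <- fit$SV
  a <- drop(fit$coefs)  # alpha_i * y_i for the support vectors
  if (config$kernel == "linear") {
    w <- drop(crossprod(sv, a))
    return(w^2)
  }
  dmat <- as.matrix(stats::dist(sv))^2
  K <- exp(-config$gamma * dmat)
  W <- tcrossprod(a) * K
  rfe_rbf_criteria(sv, W, config$gamma)
}

#' Rank features by SVM-RFE (+ CBR)
#'
#' Runs the full recursive elimination until every feature is ordered.
#' Deterministic for fixed inputs and configuration.
#'
#' @param X numeric feature matrix (standardize first; see
#'   [standardize()]).
#' @param y binary label vector (0/1), both classes present.
#' @param config a [selection_config()].
#' @return A `feature_ranking`: list with `order` (column indices, best
#'   first), `round_eliminated` (per feature), `rounds` (per-round survivor
#'   counts) and `config`.
#' @export
rfe_rank <- function(X, y, config = selection_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("feature ranking needs both classes present in 'y'")
  if (!all(is.finite(X)))
    stop("feature matrix contains non-finite values")
  d <- ncol(X)
  surviving <- seq_len(d)
  order_rev <- integer(0)          # worst-first elimination order
  round_eliminated <- integer(d)
  rounds <- integer(0)
  round <- 0L
  while (length(surviving) > 0L) {
    round <- round + 1L
    rounds <- c(rounds, length(surviving))
    if (length(surviving) == 1L) {
      round_eliminated[surviving] <- round
      order_rev <- c(order_rev, surviving)
      break
    }
    crit <- svm_rfe_criteria(X[, surviving, drop = FALSE], y, config)
    if (config$use_cbr)
      crit <- cbr_correct(crit, X[, surviving, drop = FALSE], config$rth)
    n_elim <- if (length(surviving) > config$schedule_threshold)
      length(surviving) %/% 2L else 1L
    # worst first; ties broken by column index for determinism
    ord <- order(crit, seq_along(surviving))
    worst <- ord[seq_len(n_elim)]
    elim <- surviving[worst]
    round_eliminated[elim] <- round
    order_rev <- c(order_rev, elim)
    surviving <- surviving[-worst]
  }
  structure(list(order = rev(order_rev),
                 round_eliminated = round_eliminated,
                 rounds = rounds,
                 config = config),
            class = "feature_ranking")
}

#' Top-k of a feature ranking
#'
#' @param ranking a `feature_ranking` from [rfe_rank()].
#' @param k subset size, `1 <= k <= d`.
#' @return The `k` best-ranked feature indices, best first.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  k <- as.integer(k)
  d <- length(ranking$order)
  if (k < 1L || k > d)
    stop("'k' must be between 1 and the number of ranked features (", d, ")")
  ranking$order[seq_len(k)]
}

#' Standardize, rank and select in one call
#'
#' Convenience wrapper: z-scores `X`, ranks with [rfe_rank()] and returns
#' the `config$k` best features together with the fitted scaler.
#'
#' @inheritParams rfe_rank
#' @return List with `selected` (indices), `ranking`, and `standardizer`.
#' @export
select_features <- function(X, y, config = selection_config()) {
  std <- standardize(X)
  ranking <- rfe_rank(std$X, y, config)
  k <- min(config$k, ncol(X))
  list(selected = select_top_k(ranking, k),
       ranking = ranking,
       standardizer = std$params)
}

#' Write a feature ranking as TSV
#'
#' @param ranking a `feature_ranking`.
#' @param path output path.
#' @param feature_names optional column names of the ranked matrix.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path, feature_names = NULL) {
  ord <- ranking$order
  df <- data.frame(
    rank = seq_along(ord),
    feature = if (is.null(feature_names)) ord else feature_names[ord],
    index = ord,
    round_eliminated = ranking$round_eliminated[ord])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
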
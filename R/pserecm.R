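#' @name pserecm_features
#' @title Pseudo-positional features of the energy profile
#'
#' @description
#' The pseudo-positional block summarises an L x 20 energy profile the way
#' pseudo-PSSM features summarise an evolutionary profile: the 20 per-column
#' means `mean_j = sum_i p[i,j] / L`, followed by, for each lag `l = 1..lambda`
#' and each column `j`, the mean squared difference between profile entries
#' `l` positions apart, `G[j,l] = sum_{i=1}^{L-l} (p[i,j] - p[i+l,j])^2 / (L-l)`.
#' The block has length `20 + 20*lambda` and every `G` value is non-negative.
NULL

#' Per-column means of an energy profile
#'
#' @param profile an L x 20 `sequence_energy_profile`.
#' @return Numeric vector of 20 column means, named by residue.
#' @export
column_means <- function(profile) {
  stopifnot(is.matrix(profile), ncol(profile) == 20L, nrow(profile) >= 1L)
  stats::setNames(colMeans(profile), AA_ALPHABET)
}

#' Lag correlation features of an energy profile
#'
#' Mean squared difference between profile entries a fixed number of
#' positions apart, per column and per lag `1..lambda` (lag-major order).
#'
#' @param profile an L x 20 `sequence_energy_profile`.
#' @param lambda maximum lag; must satisfy `lambda < L`.
#' @return Numeric vector of length `20 * lambda`.
#' @export
lag_correlations <- function(profile, lambda) {
  stopifnot(is.matrix(profile), ncol(profile) == 20L)
  L <- nrow(profile)
  lambda <- as.integer(lambda)
  if (lambda < 1L) stop("'lambda' must be >= 1")
  if (lambda >= L) {
    id <- attr(profile, "source_id")
    stop("lag lambda = ", lambda, " requires sequence length > lambda; ",
         if (!is.null(id) && !is.na(id)) paste0("record ", id, " ") else "",
         "has length ", L)
  }
  out <- numeric(20L * lambda)
  for (l in seq_len(lambda)) {
    d <- profile[seq_len(L - l), , drop = FALSE] -
         profile[seq.int(l + 1L, L), , drop = FALSE]
    out[(l - 1L) * 20L + seq_len(20L)] <- colMeans(d * d)
  }
  names(out) <- unlist(lapply(seq_len(lambda), function(l)
    paste0("pse.g", l, ".", AA_ALPHABET)))
  out
}

#' Pseudo-positional feature block
#'
#' Concatenation of [column_means()] and [lag_correlations()]:
#' `20 + 20*lambda` named features.
#'
#' @param profile an L x 20 `sequence_energy_profile`.
#' @param lambda maximum lag (default 5), `lambda < L`.
#' @return Named numeric vector of length `20 + 20*lambda`.
#' @export
extract_pserecm <- function(profile, lambda = 5L) {
  means <- column_means(profile)
  names(means) <- paste0("pse.mean.", AA_ALPHABET)
  c(means, lag_correlations(profile, lambda))
}
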
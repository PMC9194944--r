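#' @name dwt_features
#' @title Discrete wavelet transform features of the energy profile
#'
#' @description
#' Each of the 20 attribute columns of a sequence energy profile is treated
#' as a 1-D signal and decomposed with a cascaded two-channel filter bank
#' (`y_low[n] = sum_k x[k] g[2n-k]`, `y_high[n] = sum_k x[k] h[2n-k]`, with
#' `g`/`h` the low/high-pass decomposition filters). At every level the
#' approximation and detail bands each contribute their maximum, minimum,
#' mean and (population) standard deviation, and the approximation band
#' additionally contributes its first five discrete cosine (DCT-II)
#' coefficients: 4 + 4 + 5 = 13 features per level, 52 per column over the
#' default 4 levels, 1040 per sequence.
NULL

# Decomposition low-pass (scaling) filters; high-pass and reconstruction
# filters follow from the usual quadrature-mirror relations.
WAVELET_DEC_LO <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469,   0.48296291314469025),
  db4  = c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
           -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157,   0.2303778133088965)
)

wavelet_filters <- function(family) {
  dec_lo <- WAVELET_DEC_LO[[family]]
  if (is.null(dec_lo))
    stop("unknown wavelet family '", family, "'; available: ",
         paste(names(WAVELET_DEC_LO), collapse = ", "))
  fl <- length(dec_lo)
  rec_lo <- rev(dec_lo)
  dec_hi <- rec_lo * rep_len(c(-1, 1), fl)
  rec_hi <- rev(dec_hi)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rec_lo, rec_hi = rec_hi, length = fl)
}

#' Wavelet decomposition settings
#'
#' @param family wavelet family: `"db4"` (default, 8-tap Daubechies),
#'   `"db2"` or `"haar"`.
#' @param levels number of decomposition levels (default 4).
#' @param boundary signal extension mode: `"symmetric"` (default,
#'   whole-sample reflection) or `"periodic"` (periodization; preserves
#'   energy for orthogonal families).
#' @return A `wavelet_spec` list.
#' @export
wavelet_spec <- function(family = "db4", levels = 4L,
                         boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  levels <- as.integer(levels)
  if (levels < 1L) stop("'levels' must be >= 1")
  wavelet_filters(family)  # validates the family
  structure(list(family = family, levels = levels, boundary = boundary),
            class = "wavelet_spec")
}

# valid (non-extended) convolution of x with filter f
conv_valid <- function(x, f) {
  fl <- length(f)
  if (length(x) == fl) return(sum(x * rev(f)))
  drop(stats::embed(x, fl) %*% f)
}

min_signal_length <- function(fl, boundary) {
  if (boundary == "symmetric") fl - 1L else fl %/% 2L
}

# single analysis step: one level of filtering + dyadic downsampling
dwt_step <- function(x, filters, boundary) {
  n <- length(x)
  fl <- filters$length
  if (boundary == "symmetric") {
    if (n < fl - 1L)
      stop("signal of length ", n, " is too short for a length-", fl,
           " filter under symmetric extension (minimum ", fl - 1L, ")")
    ext <- c(rev(x[seq_len(fl - 1L)]), x, rev(x[seq(n - fl + 2L, n)]))
  } else {
    e <- fl %/% 2L
    if (n < e)
      stop("signal of length ", n, " is too short for a length-", fl,
           " filter under periodic extension (minimum ", e, ")")
    if (n %% 2L == 1L) {
      x <- c(x, x[n])
      n <- n + 1L
    }
    ext <- c(x[seq(n - e + 1L, n)], x, x[seq_len(e)])
  }
  lo <- conv_valid(ext, filters$dec_lo)
  hi <- conv_valid(ext, filters$dec_hi)
  keep <- seq.int(2L, length(lo), by = 2L)
  list(cA = lo[keep], cD = hi[keep])
}

# single synthesis step (symmetric boundary); used by reconstruction tests
idwt_step <- function(cA, cD, filters, n) {
  fl <- filters$length
  up <- function(c) {
    u <- numeric(2L * length(c))
    u[seq.int(1L, length(u), by = 2L)] <- c
    u
  }
  full_conv <- function(u, f) {
    ext <- c(numeric(fl - 1L), u, numeric(fl - 1L))
    conv_valid(ext, f)
  }
  rec <- full_conv(up(cA), filters$rec_lo) + full_conv(up(cD), filters$rec_hi)
  rec[seq.int(fl - 1L, length.out = n)]
}

#' Multi-level wavelet decomposition of one signal
#'
#' Cascades the two-channel filter bank `spec$levels` times, each level
#' re-decomposing the previous approximation band.
#'
#' @param signal numeric vector (one attribute column of an energy profile).
#' @param spec a [wavelet_spec()].
#' @return A `band_decomposition`: list with `levels` (per level, `approx`
#'   and `detail` coefficient vectors), `input_length` and `spec`.
#' @export
decompose_column <- function(signal, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (!is.numeric(signal) || length(signal) == 0L)
    stop("'signal' must be a non-empty numeric vector")
  filters <- wavelet_filters(spec$family)
  min_len <- min_signal_length(filters$length, spec$boundary)
  if (length(signal) < min_len)
    stop("signal of length ", length(signal), " is below the minimum length ",
         min_len, " for family '", spec$family, "' with ", spec$boundary,
         " boundary")
  boundary <- if (spec$boundary == "symmetric") "symmetric" else "periodic"
  out <- vector("list", spec$levels)
  cur <- signal
  for (j in seq_len(spec$levels)) {
    st <- dwt_step(cur, filters, boundary)
    out[[j]] <- list(approx = st$cA, detail = st$cD)
    cur <- st$cA
  }
  structure(list(levels = out, input_length = length(signal), spec = spec),
            class = "band_decomposition")
}

#' Band summary statistics
#'
#' Maximum, minimum, mean and population standard deviation of a
#' coefficient band, in that fixed order. The population convention
#' (divide by n) keeps length-1 bands well-defined (sd = 0).
#'
#' @param coeffs non-empty numeric vector.
#' @return Numeric vector of length 4, named `max`, `min`, `mean`, `sd`.
#' @export
band_statistics <- function(coeffs) {
  if (!is.numeric(coeffs) || length(coeffs) == 0L)
    stop("'coeffs' must be a non-empty numeric vector")
  m <- mean(coeffs)
  c(max = max(coeffs), min = min(coeffs), mean = m,
    sd = sqrt(mean((coeffs - m)^2)))
}

# unnormalised DCT-II: y_k = 2 * sum_n x_n cos(pi*k*(2n+1)/(2N)), k = 0..N-1
dct_ii <- function(x) {
  n <- length(x)
  k <- seq_len(n) - 1
  2 * drop(cos(pi / (2 * n) * outer(k, 2 * (seq_len(n) - 1) + 1)) %*% x)
}

#' Leading discrete cosine coefficients of an approximation band
#'
#' First `k` coefficients of the (unnormalised) type-II discrete cosine
#' transform; bands shorter than `k` are zero-padded on the right.
#'
#' @param approx numeric approximation-band vector.
#' @param k number of coefficients (default 5).
#' @return Numeric vector of length `k`.
#' @export
dct_leading_coefficients <- function(approx, k = 5L) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (length(approx) == 0L) return(numeric(k))
  d <- dct_ii(approx)
  out <- numeric(k)
  out[seq_len(min(k, length(d)))] <- d[seq_len(min(k, length(d)))]
  out
}

dwt_feature_names <- function(levels = 4L, dct_k = 5L,
                              alphabet = AA_ALPHABET) {
  per_level <- c(paste0("a.", c("max", "min", "mean", "sd")),
                 paste0("d.", c("max", "min", "mean", "sd")),
                 paste0("dct", seq_len(dct_k)))
  unlist(lapply(alphabet, function(res)
    unlist(lapply(seq_len(levels), function(j)
      paste0("dwt.", res, ".l", j, ".", per_level)))))
}

#' Wavelet feature block of one energy profile
#'
#' For each of the 20 attribute columns: decompose to `spec$levels` levels
#' and emit, per level, the 4 approximation-band statistics, the 4
#' detail-band statistics and the first `dct_k` discrete cosine
#' coefficients of the approximation band. With the defaults (4 levels,
#' 5 DCT coefficients) this yields 52 features per column and 1040 per
#' sequence. Feature order is column-major (all features of attribute A,
#' then C, ...), level-major within a column.
#'
#' @param profile a `sequence_energy_profile` from [encode_sequence()].
#' @param spec a [wavelet_spec()].
#' @param dct_k leading DCT coefficients kept per level (default 5).
#' @param dct_mode `"dct"` (default): DCT-II of the approximation band;
#'   `"truncate"`: the band's first `dct_k` elements instead.
#' @return Named numeric vector of length `(8 + dct_k) * levels * 20`.
#' @export
extract_dwt_features <- function(profile, spec = wavelet_spec(),
                                 dct_k = 5L,
                                 dct_mode = c("dct", "truncate")) {
  dct_mode <- match.arg(dct_mode)
  stopifnot(is.matrix(profile), ncol(profile) == 20L)
  dct_k <- as.integer(dct_k)
  vals <- lapply(seq_len(20L), function(col) {
    dec <- decompose_column(profile[, col], spec)
    unlist(lapply(dec$levels, function(lv) {
      dct_in <- lv$approx
      dct_part <- if (dct_mode == "dct") {
        dct_leading_coefficients(dct_in, dct_k)
      } else {
        out <- numeric(dct_k)
        out[seq_len(min(dct_k, length(dct_in)))] <-
          dct_in[seq_len(min(dct_k, length(dct_in)))]
        out
      }
      c(band_statistics(lv$approx), band_statistics(lv$detail), dct_part)
    }))
  })
  stats::setNames(unlist(vals),
                  dwt_feature_names(spec$levels, dct_k))
}
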
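#' Full feature matrix for a set of protein records
#'
#' Encodes every record as an energy profile and concatenates the wavelet
#' block (1040 features with the defaults) and the pseudo-positional block
#' (`20 + 20*lambda` features). Features depend only on the residue string,
#' never on ids or labels.
#'
#' @param records list of `protein_record`s (or plain sequence strings).
#' @param spec a [wavelet_spec()].
#' @param lambda pseudo-positional maximum lag (default 5).
#' @param dct_k leading DCT coefficients per level (default 5).
#' @param dct_mode see [extract_dwt_features()].
#' @return An n x d numeric matrix, rows named by record id, columns by
#'   feature name; attribute `config` records the extraction settings.
#' @export
extract_features <- function(records, spec = wavelet_spec(), lambda = 5L,
                             dct_k = 5L, dct_mode = c("dct", "truncate")) {
  dct_mode <- match.arg(dct_mode)
  if (inherits(records, "protein_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    profile <- encode_sequence(r)
    c(extract_dwt_features(profile, spec, dct_k, dct_mode),
      extract_pserecm(profile, lambda))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (inherits(r, "protein_record")) r$id else paste0("seq", i)
  }, "")
  attr(X, "config") <- list(family = spec$family, levels = spec$levels,
                            boundary = spec$boundary, lambda = lambda,
                            dct_k = dct_k, dct_mode = dct_mode)
  X
}

#' Write / read a feature matrix as TSV
#'
#' The TSV has an `id` column followed by one named column per feature, so
#' selection and training stages can run from persisted features.
#'
#' @param X feature matrix from [extract_features()].
#' @param path file path.
#' @return `path` invisibly, or the feature matrix.
#' @export
write_features_tsv <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df$id
  X
}
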
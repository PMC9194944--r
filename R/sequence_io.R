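#' @name sequence_io
#' @title Reading, validating and writing protein sequences
#'
#' @description
#' All downstream feature extraction consumes validated `protein_record`
#' lists: upper-case sequences over the 20 standard residue letters, unique
#' ids, and an optional binary label (1 = resistance protein, 0 = non-R).
#' Labels normally come from which file a sequence lives in
#' (`positive.fasta` / `negative.fasta`); a two-column id/label TSV is also
#' accepted.
NULL

new_protein_record <- function(id, sequence, label = NA_integer_) {
  structure(list(id = id, sequence = sequence, label = label),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  (%d aa, label = %s)\n",
              x$id, nchar(x$sequence),
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Validate a raw protein sequence
#'
#' Upper-cases the sequence and enforces the 20-letter amino-acid alphabet.
#' Under `"strict"` any other letter is an error; under `"drop-ambiguous"`
#' letters outside the alphabet (X, B, Z, U, O, `*`, gaps, ...) are removed
#' with a warning.
#'
#' @param raw a single non-empty string.
#' @param policy `"strict"` (default) or `"drop-ambiguous"`.
#' @param id optional record id used in error messages.
#' @return The validated upper-case sequence string.
#' @export
#' @examples
#' validate_sequence("mkv")                       # "MKV"
#' validate_sequence("MKXV", "drop-ambiguous")    # "MKV", with a warning
validate_sequence <- function(raw, policy = c("strict", "drop-ambiguous"),
                              id = NULL) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("sequence must be a single non-empty string",
         if (!is.null(id)) paste0(" (record ", id, ")"))
  s <- toupper(raw)
  letters_ <- strsplit(s, "", fixed = TRUE)[[1L]]
  ok <- letters_ %in% AA_ALPHABET
  if (all(ok)) return(s)
  who <- if (is.null(id)) "" else paste0(" in record ", id)
  if (policy == "strict") {
    stop("non-standard residue(s) ",
         paste(unique(letters_[!ok]), collapse = ", "), who,
         "; use policy = 'drop-ambiguous' to remove them")
  }
  warning("dropping ", sum(!ok), " ambiguous residue(s)", who)
  s <- paste(letters_[ok], collapse = "")
  if (!nzchar(s))
    stop("sequence is empty after dropping ambiguous residues", who)
  s
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a list of validated
#' `protein_record`s, in file order. Parsing is delegated to
#' [Biostrings::readBStringSet()]; validation and labelling happen here.
#'
#' @param path path to a FASTA file.
#' @param label optional binary label (0/1) applied to every record.
#' @param policy residue validation policy, see [validate_sequence()].
#' @return A list of `protein_record`s.
#' @export
read_fasta <- function(path, label = NA_integer_,
                       policy = c("strict", "drop-ambiguous")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop("label must be 0, 1 or NA")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no sequences found in ", path)
  ids <- names(set)
  # FASTA headers: take the first whitespace-delimited token as the id
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- unname(as.character(set))
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    records[[i]] <- new_protein_record(
      id = ids[i],
      sequence = validate_sequence(seqs[i], policy, id = ids[i]),
      label = as.integer(label))
  }
  records
}

#' Read a labelled two-class dataset
#'
#' Reads positive and negative FASTA files (labels 1 and 0), or one FASTA
#' plus a two-column `id<TAB>label` table.
#'
#' @param positive,negative paths to the two class FASTA files.
#' @param fasta,labels alternatively, one FASTA and a TSV of id/label pairs.
#' @param policy residue validation policy.
#' @return A list of labelled `protein_record`s (positives first when two
#'   FASTA files are given).
#' @export
read_dataset <- function(positive = NULL, negative = NULL,
                         fasta = NULL, labels = NULL,
                         policy = c("strict", "drop-ambiguous")) {
  policy <- match.arg(policy)
  if (!is.null(positive) || !is.null(negative)) {
    if (is.null(positive) || is.null(negative))
      stop("both 'positive' and 'negative' FASTA files are required")
    recs <- c(read_fasta(positive, label = 1L, policy = policy),
              read_fasta(negative, label = 0L, policy = policy))
  } else {
    if (is.null(fasta) || is.null(labels))
      stop("supply either positive+negative FASTA files, or fasta+labels")
    recs <- read_fasta(fasta, policy = policy)
    tab <- read.delim(labels, header = FALSE, col.names = c("id", "label"),
                      colClasses = c("character", "integer"))
    if (!all(tab$label %in% c(0L, 1L)))
      stop("labels table must contain only 0/1 labels")
    lut <- stats::setNames(tab$label, tab$id)
    for (i in seq_along(recs)) {
      lab <- lut[recs[[i]]$id]
      if (is.na(lab)) stop("no label for record ", recs[[i]]$id)
      recs[[i]]$label <- unname(lab)
    }
  }
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate ids across input files: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records a list of `protein_record`s.
#' @param path output path.
#' @param width line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# label vector helper used across modules
record_labels <- function(records) {
  vapply(records, function(r) as.integer(r$label), 1L)
}

record_ids <- function(records) {
  vapply(records, `[[`, "", "id")
}
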
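#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings that return plain named character
#' vectors (one element per record). Symbols are validated against the 20
#' amino acids plus `-` and `X`; lowercase input is normalized to uppercase
#' with a notice.
#'
#' @param path File path.
#' @param records Named character vector of sequences.
#' @return `read_fasta()`: named character vector. `write_fasta()`: the
#'   path, invisibly.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")])))
    message("lowercase residues normalized to uppercase")
  set <- Biostrings::readAAStringSet(path)
  out <- stats::setNames(as.character(set), names(set))
  validate_symbols(out)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.character(records), !is.null(names(records)))
  set <- Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

validate_symbols <- function(records) {
  if (any(grepl("[a-z]", records))) {
    message("lowercase residues normalized to uppercase")
    records <- toupper(records)
  }
  ok <- paste0(c(amino_acids(), "X"), collapse = "")
  bad <- regexpr(sprintf("[^%s-]", ok), records)  # "-" last: literal gap
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("record '%s' has illegal symbol '%s' at position %d",
                 names(records)[i], substr(records[i], bad[i], bad[i]),
                 bad[i]), call. = FALSE)
  }
  records
}

#' Read or write an alignment as aligned FASTA
#'
#' Alignments are represented as character matrices (rows = sequences,
#' columns = alignment columns, gap character `-`). A ragged input is an
#' error naming the offending record.
#'
#' @param path File path.
#' @param alignment Character matrix with rownames, or named character
#'   vector of equal-length aligned strings.
#' @return `read_alignment()`: character matrix with rownames.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta(path)
  as_alignment(recs)
}

#' @rdname read_alignment
#' @export
write_alignment <- function(alignment, path) {
  alignment <- as_alignment(alignment)
  write_fasta(apply(alignment, 1, paste0, collapse = ""), path)
}

#' @rdname read_alignment
#' @export
as_alignment <- function(alignment) {
  if (is.matrix(alignment)) {
    storage.mode(alignment) <- "character"
    return(alignment)
  }
  stopifnot(is.character(alignment), length(alignment) >= 1)
  w <- nchar(alignment)
  if (length(unique(w)) != 1) {
    off <- names(alignment)[which(w != w[1])[1]]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 off, w[w != w[1]][1], w[1]), call. = FALSE)
  }
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

# tab-separated report writer; metadata lines are "#"-prefixed
write_tsv_report <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
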
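#' @title FASTA and table I/O
#' @description Readers/writers and the coordinate conventions shared by the
#'   whole pipeline. Sequences live in memory as named character vectors over
#'   the alphabet A/C/G/T/N (RNA input is transliterated U -> T on read); all
#'   intervals are 0-based half-open. 1-based closed coordinates appear only in
#'   report columns suffixed `_1based`.
#' @name core_io
NULL

.VALID_CHARS <- c("A", "C", "G", "T", "N")

#' Log a message to standard error with an ISO-8601 timestamp
#' @param ... pieces pasted into the message
#' @keywords internal
log_msg <- function(...) {
  ts <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  message(sprintf("[%s] %s", ts, paste0(...)))
}

#' Validate a set of sequence records
#'
#' @param seqs named character vector of sequences
#' @return the validated (upper-cased) vector, invisibly usable
#' @keywords internal
validate_seqs <- function(seqs) {
  if (length(seqs) == 0) stop("empty sequence set")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must have a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[[1L]])
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id ", ids[which(!nzchar(seqs))[1L]])
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of sequence '%s'",
                 substr(seqs[[i]], bad[[i]], bad[[i]]), bad[[i]], ids[[i]]))
  }
  seqs
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased, U is transliterated to T (RNA is stored as DNA
#' throughout the package), ids must be unique and characters restricted to
#' A/C/G/T/N (after U -> T).
#'
#' @param path path to a (multi-)FASTA file
#' @return named character vector, one element per record; descriptions (text
#'   after the first whitespace of each header) are kept in the
#'   `"desc"` attribute
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(x))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    log_msg("read_fasta: transliterating U -> T in ", path)
    seqs <- chartr("U", "T", seqs)
  }
  names(seqs) <- ids
  seqs <- validate_seqs(seqs)
  attr(seqs, "desc") <- setNames(desc, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector over A/C/G/T/N
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- validate_seqs(seqs)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Write a report table as TSV
#'
#' Tab-separated with a header row; floats rendered with 6 significant digits;
#' rows written in input order. Accepts a data.frame or a list of same-field
#' records.
#'
#' @param rows data.frame, or list of named lists sharing one field set
#' @param path output path
#' @param schema character vector of column names, required when `rows` is
#'   empty so a header-only file can be written
#' @return `path`, invisibly
#' @export
write_table <- function(rows, path, schema = NULL) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (is.list(rows)) {
    if (length(rows) == 0) {
      if (is.null(schema)) stop("empty row list requires an explicit schema")
      df <- as.data.frame(setNames(rep(list(character(0)), length(schema)), schema))
    } else {
      fields <- names(rows[[1L]])
      ok <- vapply(rows, function(r) identical(names(r), fields), logical(1))
      if (!all(ok)) stop("heterogeneous rows: row ", which(!ok)[1L],
                         " does not share the field set of row 1")
      df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    }
  } else {
    stop("rows must be a data.frame or a list of records")
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path path to a TSV file with a header row
#' @return data.frame
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "", check.names = FALSE)
}

#' Construct an interval table (0-based, half-open)
#'
#' @param seq_id,start,end,strand vectors recycled to a common length
#' @return data.frame with columns seq_id, start, end, strand
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (any(df$start < 0L)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must be > start")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

#' Reverse complement of a DNA string (N maps to N)
#' @param seq character scalar over A/C/G/T/N
#' @return character scalar
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
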
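#' @title Thymidine depletion
#' @description Cryptogenes of pan-edited mRNAs share almost no recognizable
#'   sequence with their mature transcripts in standard DNA space, because the
#'   transcripts are dominated by inserted U's. Deleting every T from both
#'   query and database projects the pair into a 3-letter space where the two
#'   are (near-)identical, making homology detectable. A position map carries
#'   hit coordinates back to the original sequence.
#' @name depletion_search
NULL

#' Delete all thymidines from a sequence, keeping a coordinate map
#'
#' @param seq character scalar (a DNA sequence over A/C/G/T/N) or a length-1
#'   named character vector as returned by [read_fasta()] subsetting
#' @param id sequence id; defaults to `names(seq)`
#' @return an object of class `depleted_seq`: list with `source_id`, `depleted`
#'   (T-free string), `index_map` (integer vector; 0-based position in the
#'   depleted string -> 0-based position in the original), and `source_len`
#' @examples
#' d <- deplete_t(c(x = "ATTACGT"))
#' d$depleted   # "AACG"
#' d$index_map  # 0 3 4 5
#' @export
deplete_t <- function(seq, id = NULL) {
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[[1L]] else "seq"
  s <- toupper(as.character(seq[[1L]]))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  keep <- which(chars != "T")
  structure(list(source_id = id,
                 depleted = paste0(chars[keep], collapse = ""),
                 index_map = keep - 1L,
                 source_len = length(chars)),
            class = "depleted_seq")
}

#' Map an interval on a depleted sequence back to original coordinates
#'
#' @param d a `depleted_seq`
#' @param start,end 0-based half-open bounds on the depleted string
#' @return data.frame interval (see [interval()]) on the original sequence:
#'   `[index_map[start], index_map[end - 1] + 1)`
#' @export
restore_interval <- function(d, start, end) {
  stopifnot(inherits(d, "depleted_seq"))
  n <- length(d$index_map)
  if (start < 0 || end <= start || end > n) {
    stop(sprintf("restore_interval: [%d,%d) out of range for depleted length %d",
                 start, end, n))
  }
  interval(d$source_id,
           d$index_map[[start + 1L]],
           d$index_map[[end]] + 1L)
}

#' @export
print.depleted_seq <- function(x, ...) {
  cat(sprintf("<depleted_seq %s: %d of %d nt retained>\n",
              x$source_id, nchar(x$depleted), x$source_len))
  invisible(x)
}
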
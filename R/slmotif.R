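#' @title Spliced-leader detection and degenerate stem-loop motif search
#' @description Nuclear mRNAs of kinetoplastids acquire a short spliced-leader
#'   (SL) sequence at their 5' end by trans-splicing. [detect_sl()] finds the
#'   best SL-reference suffix match near the transcript 5' end and attributes
#'   it to the target organism or a prey reference; [sl_fraction()] summarizes
#'   SL-positive fractions. [scan_motif()] matches degenerate patterns with
#'   paired stems (the 9S "530 loop" / 12S "A-loop" use case) and
#'   [compare_to_reference()] counts identical vs compensatory stem pairs
#'   against a reference structure.
#' @name sl_and_motifs
NULL

#' Construct an SL reference table
#'
#' @param name reference names
#' @param seq SL sequences (DNA, U as T), each at least 10 nt
#' @param source "TARGET" or "PREY" per reference
#' @return data.frame of class `sl_refs`
#' @export
sl_refs <- function(name, seq, source) {
  seq <- toupper(seq)
  stopifnot(all(nchar(seq) >= 10L), all(source %in% c("TARGET", "PREY")))
  structure(data.frame(name = name, seq = seq, source = source,
                       stringsAsFactors = FALSE),
            class = c("sl_refs", "data.frame"))
}

#' Detect a spliced-leader suffix on one transcript
#'
#' Searches the first `search_window` nt of the transcript for the best match
#' to any SUFFIX (length >= `min_suffix`) of any SL reference, tolerating up to
#' `max_mismatch` mismatches. Trans-splicing adds the SL 3' end to the mRNA,
#' so assembled transcripts carry an SL suffix, usually at offset 0. Best =
#' longest matched suffix, then fewest mismatches, then TARGET over PREY; when
#' the best TARGET and best PREY candidates tie on both criteria the call is
#' AMBIGUOUS.
#'
#' @param transcript length-1 named character vector
#' @param refs an [sl_refs()] table
#' @param max_mismatch maximum mismatches in the matched suffix
#' @param min_suffix minimum suffix length considered
#' @param search_window how far into the transcript the suffix may start
#' @return one-row data.frame (transcript_id, ref_name, offset, matched_len,
#'   mismatches, source) or NULL when no qualifying match exists
#' @export
detect_sl <- function(transcript, refs, max_mismatch = 1L, min_suffix = 10L,
                      search_window = 40L) {
  stopifnot(inherits(refs, "sl_refs"), nrow(refs) > 0)
  tid <- if (!is.null(names(transcript))) names(transcript)[[1L]] else "transcript"
  tx <- toupper(as.character(transcript[[1L]]))
  nt <- nchar(tx)
  prefix_len <- min(nt, search_window + max(nchar(refs$seq)))
  pc <- strsplit(substr(tx, 1L, prefix_len), "", fixed = TRUE)[[1L]]
  best <- NULL  # list(len, mm, source, ref, offset)
  for (r in seq_len(nrow(refs))) {
    rs <- refs$seq[[r]]
    rl <- nchar(rs)
    rc <- strsplit(rs, "", fixed = TRUE)[[1L]]
    for (L in seq(rl, min_suffix)) {
      if (!is.null(best) && L < best$len) break  # shorter can't beat longest-first
      suf <- rc[(rl - L + 1L):rl]
      if (L > length(pc)) next
      for (off in 0:min(search_window, length(pc) - L)) {
        mm <- sum(pc[(off + 1L):(off + L)] != suf)
        if (mm > max_mismatch) next
        cand <- list(len = L, mm = mm, source = refs$source[[r]],
                     ref = refs$name[[r]], offset = off)
        if (is.null(best)) { best <- cand; next }
        if (cand$len > best$len ||
            (cand$len == best$len && cand$mm < best$mm)) {
          best <- cand
        } else if (cand$len == best$len && cand$mm == best$mm &&
                   cand$source != best$source) {
          # a TARGET/PREY tie at identical quality
          if (best$source == "TARGET" || cand$source == "TARGET") {
            best$tie_sources <- TRUE
            if (cand$source == "TARGET") {
              cand$tie_sources <- TRUE
              best <- cand
            }
          }
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  source <- if (isTRUE(best$tie_sources)) "AMBIGUOUS" else best$source
  data.frame(transcript_id = tid, ref_name = best$ref, offset = best$offset,
             matched_len = best$len, mismatches = best$mm, source = source,
             stringsAsFactors = FALSE)
}

#' SL-positive fractions over a transcript set
#'
#' @param transcripts named character vector
#' @param refs an [sl_refs()] table
#' @param ... passed to [detect_sl()]
#' @return list with `calls` (per-transcript call table) and `summary`
#'   (data.frame: source in TARGET/PREY/AMBIGUOUS/NONE, count, fraction;
#'   counts partition the transcript set)
#' @export
sl_fraction <- function(transcripts, refs, ...) {
  stopifnot(length(transcripts) > 0)
  calls <- list()
  src <- character(length(transcripts))
  for (i in seq_along(transcripts)) {
    call <- detect_sl(transcripts[i], refs, ...)
    if (is.null(call)) {
      src[i] <- "NONE"
    } else {
      src[i] <- call$source
      calls[[length(calls) + 1L]] <- call
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(transcript_id = character(0), ref_name = character(0),
               offset = integer(0), matched_len = integer(0),
               mismatches = integer(0), source = character(0),
               stringsAsFactors = FALSE)
  lev <- c("TARGET", "PREY", "AMBIGUOUS", "NONE")
  counts <- table(factor(src, levels = lev))
  summary <- data.frame(source = lev, count = as.integer(counts),
                        fraction = as.numeric(counts) / length(transcripts),
                        stringsAsFactors = FALSE)
  list(calls = calls, summary = summary)
}

# ---------------------------------------------------------------------------
# degenerate motif patterns with paired stems

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Motif pattern elements
#'
#' Build blocks for [motif_pattern()]: a literal IUPAC string with a mismatch
#' budget, an unconstrained gap with a length range, and paired stem halves.
#' A `motif_stem_close(id, ...)` must reference an earlier
#' `motif_stem_open(id, ...)`; the closing half must base-pair with the
#' opening half read antiparallel (Watson-Crick, plus G:U when `allow_gu`),
#' tolerating up to `max_mispair` non-pairing columns.
#'
#' @param iupac literal pattern (IUPAC codes)
#' @param max_mismatch mismatch budget of the literal
#' @param id stem identifier linking open/close halves
#' @param len_min,len_max stem or gap length range
#' @param max_mispair tolerated non-pairing stem columns
#' @param allow_gu whether G:U counts as pairing in the stem
#' @return an element list for [motif_pattern()]
#' @name motif_elements
NULL

#' @rdname motif_elements
#' @export
motif_literal <- function(iupac, max_mismatch = 0L) {
  iupac <- toupper(iupac)
  stopifnot(all(strsplit(iupac, "")[[1L]] %in% names(.IUPAC)))
  list(type = "LITERAL", iupac = iupac, max_mismatch = as.integer(max_mismatch))
}

#' @rdname motif_elements
#' @export
motif_gap <- function(len_min, len_max = len_min) {
  stopifnot(len_min >= 0L, len_max >= len_min)
  list(type = "GAP", len_min = as.integer(len_min), len_max = as.integer(len_max))
}

#' @rdname motif_elements
#' @export
motif_stem_open <- function(id, len_min, len_max = len_min) {
  stopifnot(len_min >= 1L, len_max >= len_min)
  list(type = "STEM_OPEN", id = as.character(id),
       len_min = as.integer(len_min), len_max = as.integer(len_max))
}

#' @rdname motif_elements
#' @export
motif_stem_close <- function(id, max_mispair = 0L, allow_gu = TRUE) {
  list(type = "STEM_CLOSE", id = as.character(id),
       max_mispair = as.integer(max_mispair), allow_gu = isTRUE(allow_gu))
}

#' Compile a motif pattern
#'
#' @param ... elements from [motif_literal()], [motif_gap()],
#'   [motif_stem_open()], [motif_stem_close()], in 5'-to-3' order
#' @return validated pattern of class `motif_pattern`
#' @export
motif_pattern <- function(...) {
  elements <- list(...)
  if (!length(elements)) stop("empty motif pattern")
  open_ids <- character(0)
  for (e in elements) {
    if (!is.list(e) || is.null(e$type)) stop("malformed pattern element")
    if (e$type == "STEM_OPEN") {
      if (e$id %in% open_ids) stop("duplicate stem id ", e$id)
      open_ids <- c(open_ids, e$id)
    }
    if (e$type == "STEM_CLOSE" && !e$id %in% open_ids) {
      stop("STEM_CLOSE '", e$id, "' does not reference a prior STEM_OPEN")
    }
  }
  structure(list(elements = elements), class = "motif_pattern")
}

#' Parse a motif pattern file
#'
#' One element per line, whitespace-separated fields; `#` starts a comment.
#' Lines: `literal <iupac> [max_mismatch]`, `gap <min> [max]`,
#' `stem_open <id> <len_min> [len_max]`, `stem_close <id> [max_mispair] [gu|nogu]`.
#'
#' @param path path to the pattern file
#' @return a [motif_pattern()]
#' @export
parse_motif_pattern <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  els <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\\s+")[[1L]]
    switch(tolower(f[[1L]]),
           literal = motif_literal(f[[2L]],
                                   if (length(f) > 2L) as.integer(f[[3L]]) else 0L),
           gap = motif_gap(as.integer(f[[2L]]),
                           if (length(f) > 2L) as.integer(f[[3L]]) else as.integer(f[[2L]])),
           stem_open = motif_stem_open(f[[2L]], as.integer(f[[3L]]),
                                       if (length(f) > 3L) as.integer(f[[4L]]) else as.integer(f[[3L]])),
           stem_close = motif_stem_close(f[[2L]],
                                         if (length(f) > 2L) as.integer(f[[3L]]) else 0L,
                                         if (length(f) > 3L) tolower(f[[4L]]) == "gu" else TRUE),
           stop("unknown pattern element: ", f[[1L]]))
  })
  do.call(motif_pattern, els)
}

.iupac_match <- function(seq_chars, iupac_chars) {
  ok <- mapply(function(s, p) s %in% .IUPAC[[p]], seq_chars, iupac_chars)
  sum(!ok)
}

.pairs_ok <- function(a, b, allow_gu) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  wc
}

# recursive matcher; returns list of matches, each a list of element records
.match_elements <- function(chars, pos, elements, ei, stems, acc) {
  if (ei > length(elements)) return(list(acc))
  e <- elements[[ei]]
  out <- list()
  n <- length(chars)
  if (e$type == "LITERAL") {
    L <- nchar(e$iupac)
    if (pos + L - 1L <= n) {
      mm <- .iupac_match(chars[pos:(pos + L - 1L)],
                         strsplit(e$iupac, "")[[1L]])
      if (mm <= e$max_mismatch) {
        rec <- list(type = "LITERAL", start = pos, end = pos + L - 1L)
        out <- c(out, .match_elements(chars, pos + L, elements, ei + 1L,
                                      stems, c(acc, list(rec))))
      }
    }
  } else if (e$type == "GAP") {
    for (L in e$len_min:e$len_max) {
      if (L > 0L && pos + L - 1L > n) break
      rec <- list(type = "GAP", start = pos, end = pos + L - 1L)
      out <- c(out, .match_elements(chars, pos + L, elements, ei + 1L,
                                    stems, c(acc, list(rec))))
    }
  } else if (e$type == "STEM_OPEN") {
    for (L in e$len_min:e$len_max) {
      if (pos + L - 1L > n) break
      stems2 <- stems
      stems2[[e$id]] <- list(start = pos, len = L)
      rec <- list(type = "STEM_OPEN", id = e$id, start = pos, end = pos + L - 1L)
      out <- c(out, .match_elements(chars, pos + L, elements, ei + 1L,
                                    stems2, c(acc, list(rec))))
    }
  } else if (e$type == "STEM_CLOSE") {
    op <- stems[[e$id]]
    L <- op$len
    if (pos + L - 1L <= n) {
      a <- chars[op$start:(op$start + L - 1L)]
      b <- chars[(pos + L - 1L):pos]  # antiparallel
      mis <- sum(!.pairs_ok(a, b, e$allow_gu))
      if (mis <= e$max_mispair) {
        rec <- list(type = "STEM_CLOSE", id = e$id, start = pos,
                    end = pos + L - 1L, mispairs = mis)
        out <- c(out, .match_elements(chars, pos + L, elements, ei + 1L,
                                      stems, c(acc, list(rec))))
      }
    }
  }
  out
}

#' Scan a sequence for a degenerate stem-loop motif
#'
#' Elements are matched in order on both strands; stems must base-pair
#' antiparallel (Watson-Crick, plus G:U when allowed). Overlapping occurrences
#' on the same strand are resolved leftmost-first.
#'
#' @param seq length-1 named character vector
#' @param pattern a [motif_pattern()]
#' @return object of class `motif_hits`: list with `hits` (data.frame: seq_id,
#'   strand, start, end in scanned-strand coordinates plus orig_start/orig_end
#'   on the input strand, n_elements) and `matches` (per-hit element records
#'   incl. stem pair tables used by [compare_to_reference()])
#' @export
scan_motif <- function(seq, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  sid <- if (!is.null(names(seq))) names(seq)[[1L]] else "seq"
  s <- toupper(as.character(seq[[1L]]))
  n <- nchar(s)
  hit_rows <- list(); match_recs <- list()
  for (strand in c("+", "-")) {
    str_seq <- if (strand == "+") s else revcomp(s)
    chars <- strsplit(str_seq, "", fixed = TRUE)[[1L]]
    taken <- logical(n)
    for (start in seq_len(n)) {
      if (taken[start]) next
      ms <- .match_elements(chars, start, pattern$elements, 1L, list(), list())
      if (!length(ms)) next
      m <- ms[[1L]]  # leftmost, then first (shortest-gap) expansion
      end <- max(vapply(m, function(r) r$end, numeric(1)))
      if (any(taken[start:end])) next
      taken[start:end] <- TRUE
      orig <- if (strand == "+") c(start - 1L, end) else
        c(n - end, n - start + 1L)
      orig <- as.integer(orig)
      stems <- list()
      opens <- Filter(function(r) r$type == "STEM_OPEN", m)
      closes <- Filter(function(r) r$type == "STEM_CLOSE", m)
      for (cl in closes) {
        op <- Filter(function(r) r$id == cl$id, opens)[[1L]]
        L <- op$end - op$start + 1L
        stems[[cl$id]] <- data.frame(
          base5 = chars[op$start:(op$start + L - 1L)],
          base3 = chars[(cl$end):(cl$start)],
          stringsAsFactors = FALSE)
      }
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        seq_id = sid, strand = strand,
        start = orig[1L], end = orig[2L],
        n_elements = length(m), stringsAsFactors = FALSE)
      match_recs[[length(match_recs) + 1L]] <-
        list(strand = strand, elements = m, stems = stems)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(seq_id = character(0), strand = character(0),
               start = integer(0), end = integer(0), n_elements = integer(0),
               stringsAsFactors = FALSE)
  structure(list(hits = hits, matches = match_recs), class = "motif_hits")
}

#' Compare a motif hit's stems with a reference pairing
#'
#' A stem column is "identical" when the hit pairs with the same nucleotide
#' pair as the reference, and "compensatory" when both structures pair at that
#' column (Watson-Crick or G:U) but with different pairs; tolerated mispairs
#' count as neither.
#'
#' @param hit a `motif_hits` object from [scan_motif()]
#' @param reference_pairs data.frame with columns `base5`, `base3`: the
#'   reference stem columns, concatenated over stems in pattern order
#' @param which_hit index of the hit to compare (default 1)
#' @return data.frame: n_columns, n_identical, n_compensatory
#' @export
compare_to_reference <- function(hit, reference_pairs, which_hit = 1L) {
  stopifnot(inherits(hit, "motif_hits"), length(hit$matches) >= which_hit)
  stems <- hit$matches[[which_hit]]$stems
  if (!length(stems)) stop("hit has no stems")
  obs <- do.call(rbind, stems)
  if (nrow(obs) != nrow(reference_pairs)) {
    stop("reference pairing has ", nrow(reference_pairs),
         " columns but hit stems have ", nrow(obs))
  }
  obs_pair <- .pairs_ok(obs$base5, obs$base3, allow_gu = TRUE)
  ref_pair <- .pairs_ok(toupper(reference_pairs$base5),
                        toupper(reference_pairs$base3), allow_gu = TRUE)
  same <- obs$base5 == toupper(reference_pairs$base5) &
    obs$base3 == toupper(reference_pairs$base3)
  n_identical <- sum(same & obs_pair & ref_pair)
  n_compensatory <- sum(!same & obs_pair & ref_pair)
  data.frame(n_columns = nrow(obs), n_identical = n_identical,
             n_compensatory = n_compensatory)
}
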
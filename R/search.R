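#' @title Seed-and-extend homology search
#' @description Local nucleotide search used throughout the pipeline, in two
#'   flavours: [local_search()] over the standard 4-letter alphabet, and
#'   [tdepleted_search()] over the T-depleted 3-letter projection used to
#'   locate cryptogenes of pan-edited mRNAs. Both use exact k-mer seeding,
#'   diagonal chaining, ungapped x-drop extension and gapped refinement, with
#'   no low-complexity masking. Both strands of the database are searched by
#'   reverse-complementing the subject, never the query; all reported
#'   coordinates are 0-based half-open on the ORIGINAL sequences.
#' @name homology_search
NULL

#' Search parameters
#'
#' @param seed_len exact k-mer seed length. Defaults: 12 in standard space, 10
#'   in depleted space (the 3-letter alphabet has lower per-position entropy).
#'   Small seeds (down to 4) are supported for maximum sensitivity.
#' @param min_hit_len minimum alignment length in columns of the search space
#' @param min_identity minimum identity (matches / alignment columns, gaps
#'   count as columns) computed in the search space
#' @param xdrop x-drop threshold for ungapped seed extension
#' @param max_hits cap on reported hits
#' @param band half-width of the window padding around the extended seed
#'   region used for gapped refinement
#' @return list of class `search_params`
#' @export
search_params <- function(seed_len = 12L, min_hit_len = 50L, min_identity = 0.8,
                          xdrop = 20, max_hits = 100L, band = 15L) {
  stopifnot(seed_len >= 4L, min_identity > 0, min_identity <= 1, min_hit_len >= 1L)
  structure(list(seed_len = as.integer(seed_len),
                 min_hit_len = as.integer(min_hit_len),
                 min_identity = min_identity, xdrop = xdrop,
                 max_hits = as.integer(max_hits), band = as.integer(band)),
            class = "search_params")
}

.sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c("A", "C", "G", "T", "N")
      mm <- matrix(-3, 5, 5, dimnames = list(letters, letters))
      diag(mm) <- 2
      mm["N", "N"] <- -3  # N never matches anything
      m <<- mm
    }
    m
  }
})

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), length = integer(0),
             identity = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# shared k-mer positions between query and subject (1-based starts)
.seed_pairs <- function(q, s, k) {
  nq <- nchar(q); ns <- nchar(s)
  if (nq < k || ns < k) return(NULL)
  qk <- substring(q, 1:(nq - k + 1L), k:nq)
  sk <- substring(s, 1:(ns - k + 1L), k:ns)
  okq <- !grepl("N", qk, fixed = TRUE)
  qtab <- split(which(okq), qk[okq])
  oks <- which(!grepl("N", sk, fixed = TRUE))
  hit <- qtab[sk[oks]]
  found <- !vapply(hit, is.null, logical(1))
  if (!any(found)) return(NULL)
  hit <- hit[found]
  spos <- oks[found]
  data.frame(qpos = unlist(hit, use.names = FALSE),
             spos = rep.int(spos, lengths(hit)))
}

# group seeds into candidate regions by diagonal proximity
.cluster_seeds <- function(seeds, band, max_gap = 1500L) {
  seeds$diag <- seeds$spos - seeds$qpos
  seeds <- seeds[order(seeds$diag, seeds$spos), , drop = FALSE]
  n <- nrow(seeds)
  newc <- c(TRUE, (diff(seeds$diag) > band) |
              (abs(diff(seeds$spos)) > max_gap))
  seeds$cluster <- cumsum(newc)
  split(seeds, seeds$cluster)
}

# ungapped x-drop extension of a bounding box along its anchor diagonal
.xdrop_extend <- function(qc, sc, q0, q1, s0, s1, xdrop) {
  nq <- length(qc); ns <- length(sc)
  # rightwards from (q1, s1)
  i <- q1; j <- s1; sc_run <- 0; best <- 0; bi <- q1; bj <- s1
  while (i < nq && j < ns) {
    i <- i + 1L; j <- j + 1L
    sc_run <- sc_run + if (qc[i] == sc[j] && qc[i] != "N") 2 else -3
    if (sc_run > best) { best <- sc_run; bi <- i; bj <- j }
    if (best - sc_run > xdrop) break
  }
  q1 <- bi; s1 <- bj
  # leftwards from (q0, s0)
  i <- q0; j <- s0; sc_run <- 0; best <- 0; bi <- q0; bj <- s0
  while (i > 1L && j > 1L) {
    i <- i - 1L; j <- j - 1L
    sc_run <- sc_run + if (qc[i] == sc[j] && qc[i] != "N") 2 else -3
    if (sc_run > best) { best <- sc_run; bi <- i; bj <- j }
    if (best - sc_run > xdrop) break
  }
  c(bi, q1, bj, s1)
}

# core search of one query string vs one subject string (same search space);
# returns hits with 1-based inclusive coordinates in that space
.search_core <- function(q, s, params) {
  seeds <- .seed_pairs(q, s, params$seed_len)
  if (is.null(seeds)) return(NULL)
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  scv <- strsplit(s, "", fixed = TRUE)[[1L]]
  k <- params$seed_len
  out <- list()
  for (cl in .cluster_seeds(seeds, params$band)) {
    # each diagonal group in the cluster is gated on its ungapped score
    # before any gapped refinement is paid for: true hits stack many seeds on
    # a diagonal (indels shift the stack to a nearby one), spurious seeds
    # scatter and rarely pass
    boxes <- list()
    for (grp in split(cl, cl$diag)) {
      d <- grp$diag[[1L]]
      q0 <- min(grp$qpos); q1 <- max(grp$qpos) + k - 1L
      s0 <- min(grp$spos); s1 <- max(grp$spos) + k - 1L
      ext <- .xdrop_extend(qc, scv, q0, q1, s0, s1, params$xdrop)
      qi <- max(1L, ext[1L]):min(length(qc), ext[2L])
      qi <- qi[qi + d >= 1L & qi + d <= length(scv)]
      ungapped <- sum(ifelse(qc[qi] == scv[qi + d] & qc[qi] != "N", 2L, -3L))
      if (ungapped >= 2L * k + 6L) boxes[[length(boxes) + 1L]] <- ext
    }
    if (!length(boxes)) next
    # one gapped refinement over the union of the passing boxes, so an
    # alignment may bridge nearby diagonal groups (i.e., cross indels)
    ext <- as.integer(c(min(vapply(boxes, `[`, 0, 1L)),
                        max(vapply(boxes, `[`, 0, 2L)),
                        min(vapply(boxes, `[`, 0, 3L)),
                        max(vapply(boxes, `[`, 0, 4L))))
    pad <- params$band + 10L
    qw <- c(max(1L, ext[1L] - pad), min(length(qc), ext[2L] + pad))
    sw <- c(max(1L, ext[3L] - pad), min(length(scv), ext[4L] + pad))
    aln <- Biostrings::pairwiseAlignment(
      pattern = substr(q, qw[1L], qw[2L]),
      subject = substr(s, sw[1L], sw[2L]),
      type = "local", substitutionMatrix = .sub_matrix(),
      gapOpening = 5, gapExtension = 2)
    if (Biostrings::score(aln) <= 0) next
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    pc <- strsplit(pa, "", fixed = TRUE)[[1L]]
    scc <- strsplit(sa, "", fixed = TRUE)[[1L]]
    ncols <- length(pc)
    if (ncols < params$min_hit_len) next
    ident <- sum(pc == scc & pc != "-" & pc != "N") / ncols
    if (ident < params$min_identity) next
    pr <- aln@pattern@range
    sr <- aln@subject@range
    out[[length(out) + 1L]] <- data.frame(
      qs = qw[1L] + BiocGenerics::start(pr) - 1L,
      qe = qw[1L] + BiocGenerics::end(pr) - 1L,
      ss = sw[1L] + BiocGenerics::start(sr) - 1L,
      se = sw[1L] + BiocGenerics::end(sr) - 1L,
      len = ncols, identity = ident, score = Biostrings::score(aln))
  }
  if (!length(out)) return(NULL)
  hits <- do.call(rbind, out)
  # drop near-duplicate hits arising from overlapping seed clusters
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      qo <- min(hits$qe[i], hits$qe[j]) - max(hits$qs[i], hits$qs[j]) + 1L
      so <- min(hits$se[i], hits$se[j]) - max(hits$ss[i], hits$ss[j]) + 1L
      if (qo > 0.5 * (hits$qe[i] - hits$qs[i] + 1L) &&
          so > 0.5 * (hits$se[i] - hits$ss[i] + 1L)) { keep[i] <- FALSE; break }
    }
  }
  hits[keep, , drop = FALSE]
}

.finish_hits <- function(rows, params) {
  if (!length(rows)) return(.empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score, hits$subject_id, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, params$max_hits)
}

#' Local homology search in standard DNA space
#'
#' Seed-and-extend local search of one query against a database, both strands,
#' no masking. Identity is matches / alignment columns (gaps count as
#' columns); N matches nothing.
#'
#' @param query length-1 named character vector (or string; `query_id` then
#'   names it)
#' @param db named character vector of subject sequences
#' @param params a [search_params()]; default uses seed length 12
#' @param query_id id used when `query` is unnamed
#' @return data.frame with columns query_id, subject_id, q_start, q_end,
#'   s_start, s_end (0-based half-open, original coordinates), strand,
#'   identity, score; sorted by descending score (ties: subject_id, s_start)
#' @export
local_search <- function(query, db, params = search_params(), query_id = NULL) {
  qid <- if (!is.null(query_id)) query_id else if (!is.null(names(query))) names(query)[[1L]] else "query"
  q <- toupper(as.character(query[[1L]]))
  if (length(db) == 0) return(.empty_hits())
  rows <- list()
  for (sid in names(db)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") toupper(db[[sid]]) else revcomp(db[[sid]])
      h <- .search_core(q, s, params)
      if (is.null(h)) next
      L <- nchar(s)
      s_start <- if (strand == "+") h$ss - 1L else L - h$se
      s_end <- if (strand == "+") h$se else L - h$ss + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, subject_id = sid,
        q_start = h$qs - 1L, q_end = h$qe,
        s_start = s_start, s_end = s_end,
        strand = strand, length = h$len,
        identity = h$identity, score = h$score,
        stringsAsFactors = FALSE)
    }
  }
  .finish_hits(rows, params)
}

#' Homology search in thymidine-depleted space
#'
#' Both query and database are projected to their T-free form before seeding
#' and alignment; U-indel editing is invisible in this space, so a cryptogene
#' and its pan-edited mRNA align at (near-)full identity. Reported intervals
#' are mapped back through the position maps to ORIGINAL coordinates of both
#' query and subject; `identity` is computed in the depleted space.
#'
#' @inheritParams local_search
#' @param params a [search_params()]; default uses seed length 10
#' @return as [local_search()]
#' @export
tdepleted_search <- function(query, db, params = search_params(seed_len = 10L),
                             query_id = NULL) {
  qid <- if (!is.null(query_id)) query_id else if (!is.null(names(query))) names(query)[[1L]] else "query"
  dq <- deplete_t(toupper(as.character(query[[1L]])), id = qid)
  if (length(db) == 0 || nchar(dq$depleted) == 0) return(.empty_hits())
  rows <- list()
  for (sid in names(db)) {
    L <- nchar(db[[sid]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") toupper(db[[sid]]) else revcomp(db[[sid]])
      ds <- deplete_t(s, id = sid)
      if (nchar(ds$depleted) == 0) next
      h <- .search_core(dq$depleted, ds$depleted, params)
      if (is.null(h)) next
      for (r in seq_len(nrow(h))) {
        qiv <- restore_interval(dq, h$qs[r] - 1L, h$qe[r])
        siv <- restore_interval(ds, h$ss[r] - 1L, h$se[r])
        s_start <- if (strand == "+") siv$start else L - siv$end
        s_end <- if (strand == "+") siv$end else L - siv$start
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid, subject_id = sid,
          q_start = qiv$start, q_end = qiv$end,
          s_start = s_start, s_end = s_end,
          strand = strand, length = h$len[r],
          identity = h$identity[r], score = h$score[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  .finish_hits(rows, params)
}
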
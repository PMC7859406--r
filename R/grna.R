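#' @title Minicircle architecture and guide-RNA detection
#' @description Classify mitochondrial contigs into maxicircle-like (carry
#'   cryptogenes / rRNA genes) and minicircle-like (short, share a conserved
#'   backbone, carry gRNA cassettes), segment conserved backbones from
#'   variable cassettes, detect gRNA:mRNA antisense duplexes with G:U wobble
#'   pairing, and test circular-mapping by terminal-overlap detection.
#' @name grna_minicircle
NULL

#' Parameters for gRNA duplex detection
#'
#' A gRNA pairs antisense with its edited mRNA using Watson-Crick pairs plus
#' G:U wobble (gRNA G : mRNA U, or gRNA U : mRNA G). Duplexes are scored per
#' pair and must satisfy a minimum length, a minimum perfect-WC anchor run and
#' a maximum mismatch fraction. Wobble support can be switched off
#' (`allow_wobble = FALSE`) to mimic plain nucleotide similarity.
#'
#' @param min_duplex minimum duplex length (nt)
#' @param min_anchor minimum run of consecutive WC pairs anywhere in the duplex
#' @param wc_score,wobble_score,mismatch_pen per-pair scores
#' @param max_mismatch_frac maximum fraction of mismatched pairs
#' @param seed_len exact-WC k-mer length used to seed candidate diagonals
#' @param allow_wobble whether G:U wobble counts as pairing
#' @return list of class `grna_params`
#' @export
grna_params <- function(min_duplex = 25L, min_anchor = 6L,
                        wc_score = 1, wobble_score = 0.5, mismatch_pen = -1,
                        max_mismatch_frac = 0.1, seed_len = 9L,
                        allow_wobble = TRUE) {
  stopifnot(min_duplex >= min_anchor, min_anchor >= 1)
  structure(list(min_duplex = as.integer(min_duplex),
                 min_anchor = as.integer(min_anchor),
                 wc_score = wc_score, wobble_score = wobble_score,
                 mismatch_pen = mismatch_pen,
                 max_mismatch_frac = max_mismatch_frac,
                 seed_len = as.integer(seed_len),
                 allow_wobble = isTRUE(allow_wobble)),
            class = "grna_params")
}

.empty_grna_hits <- function() {
  data.frame(minicircle_id = character(0), cassette_start = integer(0),
             cassette_end = integer(0), strand = character(0),
             mrna_id = character(0), mrna_start = integer(0),
             mrna_end = integer(0), n_wc = integer(0), n_wobble = integer(0),
             n_mismatch = integer(0), anchor_len = integer(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

# longest run of TRUE
.longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# best-scoring contiguous segments of a score vector (repeated Kadane with
# masking); returns list of c(start, end) 1-based inclusive
.best_segments <- function(sc, min_score, max_segments = 10L) {
  out <- list()
  for (rep_i in seq_len(max_segments)) {
    best <- 0; bs <- 0L; be <- 0L
    run <- 0; rs <- 1L
    for (i in seq_along(sc)) {
      if (run <= 0) { run <- sc[i]; rs <- i } else run <- run + sc[i]
      if (run > best) { best <- run; bs <- rs; be <- i }
    }
    if (best < min_score || bs == 0L) break
    out[[length(out) + 1L]] <- c(bs, be)
    sc[bs:be] <- -1e9
  }
  out
}

#' Find gRNA cassettes on a minicircle by wobble-aware antisense duplex scan
#'
#' Each strand of the minicircle is compared with the reverse complement of
#' each edited mRNA, so Watson-Crick pairing becomes character identity and
#' G:U wobble becomes (gRNA G vs revcomp A) or (gRNA T vs revcomp C).
#' Candidate diagonals are seeded by exact `seed_len`-mers, scored per pair
#' and the best-scoring contiguous duplex segments extracted; overlapping
#' cassette calls are resolved to the best-scoring.
#'
#' @param minicircle length-1 named character vector
#' @param edited_mrnas named character vector of mature (edited) mRNAs
#' @param params a [grna_params()]
#' @return data.frame: minicircle_id, cassette_start, cassette_end (0-based
#'   half-open on the minicircle), strand (minicircle strand carrying the
#'   gRNA), mrna_id, mrna_start, mrna_end (block on the mRNA), n_wc,
#'   n_wobble, n_mismatch, anchor_len, score
#' @export
find_grnas <- function(minicircle, edited_mrnas, params = grna_params()) {
  mid <- if (!is.null(names(minicircle))) names(minicircle)[[1L]] else "minicircle"
  mc <- toupper(as.character(minicircle[[1L]]))
  L <- nchar(mc)
  rows <- list()
  for (strand in c("+", "-")) {
    g <- if (strand == "+") mc else revcomp(mc)
    gch <- strsplit(g, "", fixed = TRUE)[[1L]]
    for (tid in names(edited_mrnas)) {
      t <- revcomp(edited_mrnas[[tid]])
      M <- nchar(t)
      tch <- strsplit(t, "", fixed = TRUE)[[1L]]
      seeds <- .seed_pairs(g, t, params$seed_len)
      if (is.null(seeds)) next
      diags <- unique(seeds$spos - seeds$qpos)
      for (d in diags) {
        i0 <- max(1L, 1L - d); i1 <- min(L, M - d)
        if (i1 - i0 + 1L < params$min_duplex) next
        gi <- gch[i0:i1]; tj <- tch[(i0 + d):(i1 + d)]
        wc <- gi == tj & gi != "N"
        wob <- if (params$allow_wobble) {
          (gi == "G" & tj == "A") | (gi == "T" & tj == "C")
        } else rep(FALSE, length(gi))
        sc <- ifelse(wc, params$wc_score,
                     ifelse(wob, params$wobble_score, params$mismatch_pen))
        min_score <- params$min_duplex * min(params$wc_score, 1) * 0.5
        for (seg in .best_segments(sc, min_score)) {
          a <- seg[1L]; b <- seg[2L]
          len <- b - a + 1L
          if (len < params$min_duplex) next
          n_wc <- sum(wc[a:b]); n_wob <- sum(wob[a:b])
          n_mm <- len - n_wc - n_wob
          if (n_mm / len > params$max_mismatch_frac) next
          anchor <- .longest_run(wc[a:b])
          if (anchor < params$min_anchor) next
          # cassette on the searched strand, 1-based inclusive
          ga <- i0 + a - 1L; gb <- i0 + b - 1L
          cas <- if (strand == "+") c(ga - 1L, gb) else c(L - gb, L - ga + 1L)
          # block on revcomp(mRNA) -> original mRNA coordinates
          ta <- ga + d; tb <- gb + d
          mrna_iv <- c(M - tb, M - ta + 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            minicircle_id = mid, cassette_start = cas[1L], cassette_end = cas[2L],
            strand = strand, mrna_id = tid,
            mrna_start = mrna_iv[1L], mrna_end = mrna_iv[2L],
            n_wc = n_wc, n_wobble = n_wob, n_mismatch = n_mm,
            anchor_len = anchor,
            score = n_wc * params$wc_score + n_wob * params$wobble_score +
              n_mm * params$mismatch_pen,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(.empty_grna_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score, hits$mrna_id, hits$cassette_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      ov <- min(hits$cassette_end[i], hits$cassette_end[j]) -
        max(hits$cassette_start[i], hits$cassette_start[j])
      w <- min(hits$cassette_end[i] - hits$cassette_start[i],
               hits$cassette_end[j] - hits$cassette_start[j])
      if (ov > 0.5 * w) { keep[i] <- FALSE; break }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Find conserved backbone intervals shared across contigs
#'
#' A backbone position of a contig is one covered by local hits at
#' `min_identity` from at least `min_share` other contigs; runs of such
#' positions at least `min_len` long are reported, overlapping runs merged.
#'
#' @param contigs named character vector (>= 2 contigs)
#' @param min_identity minimum hit identity
#' @param min_len minimum backbone interval length (nt)
#' @param min_share minimum number of other contigs sharing the region
#' @param search search parameters for the underlying [local_search()]
#' @return named list (per contig) of interval data.frames (possibly 0-row)
#' @export
find_backbone <- function(contigs, min_identity = 0.90, min_len = 100L,
                          min_share = 2L,
                          search = search_params(min_identity = min_identity,
                                                 min_hit_len = min_len,
                                                 max_hits = 1000L)) {
  if (length(contigs) < 2L) stop("find_backbone needs >= 2 contigs")
  out <- vector("list", length(contigs))
  names(out) <- names(contigs)
  for (cid in names(contigs)) {
    n <- nchar(contigs[[cid]])
    cov <- integer(n)
    others <- contigs[setdiff(names(contigs), cid)]
    hits <- local_search(contigs[cid], others, search)
    hits <- hits[hits$identity >= min_identity &
                   (hits$q_end - hits$q_start) >= min_len, , drop = FALSE]
    for (sid in unique(hits$subject_id)) {
      covered <- logical(n)
      h <- hits[hits$subject_id == sid, , drop = FALSE]
      for (r in seq_len(nrow(h))) {
        covered[(h$q_start[r] + 1L):h$q_end[r]] <- TRUE
      }
      cov <- cov + as.integer(covered)
    }
    runs <- rle(cov >= min_share)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sel <- runs$values & runs$lengths >= min_len
    out[[cid]] <- if (any(sel)) {
      interval(cid, starts[sel] - 1L, ends[sel])
    } else interval("x", 0L, 1L)[0, ]
  }
  out
}

#' Test whether a contig maps circularly (duplicated terminus)
#'
#' @param contig length-1 named character vector
#' @param min_overlap minimum prefix/suffix overlap length
#' @param max_mismatch maximum substitutions tolerated in the overlap
#' @return list(circular = flag, overlap_len = longest qualifying overlap)
#' @export
detect_circularity <- function(contig, min_overlap = 50L, max_mismatch = 2L) {
  s <- toupper(as.character(contig[[1L]]))
  n <- nchar(s)
  if (n <= 2L * min_overlap) stop("contig shorter than 2 * min_overlap")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (L in seq(n %/% 2L, min_overlap)) {
    mm <- sum(ch[1:L] != ch[(n - L + 1L):n])
    if (mm <= max_mismatch) return(list(circular = TRUE, overlap_len = L))
  }
  list(circular = FALSE, overlap_len = 0L)
}

#' Parameters for mitochondrial contig classification
#'
#' @param minicircle_len_range plausible minicircle length range (nt);
#'   presets: 1300-2200 bp (P. ankaliazontas-like), ~600 bp
#'   (A. spiralis-like)
#' @param maxi_min_hit minimum depleted-space hit length (columns) for a
#'   cryptogene-level mRNA hit; gRNA cassettes (~85 nt, ~45 nt depleted) fall
#'   well below this
#' @param maxi_min_identity minimum depleted-space identity for mRNA evidence
#' @param rrna_min_hit,rrna_min_identity standard-space thresholds for rRNA
#'   evidence
#' @param backbone_min_identity,backbone_min_len,backbone_min_share passed to
#'   [find_backbone()]
#' @param circ_min_overlap,circ_max_mismatch passed to [detect_circularity()]
#' @return list of class `mt_class_params`
#' @export
mt_class_params <- function(minicircle_len_range = c(400L, 2500L),
                            maxi_min_hit = 100L, maxi_min_identity = 0.85,
                            rrna_min_hit = 100L, rrna_min_identity = 0.8,
                            backbone_min_identity = 0.90,
                            backbone_min_len = 100L, backbone_min_share = 2L,
                            circ_min_overlap = 50L, circ_max_mismatch = 2L) {
  structure(as.list(environment()), class = "mt_class_params")
}

#' Classify mitochondrial contigs as maxicircle-like or minicircle-like
#'
#' A contig is MAXICIRCLE_LIKE when at least one mature mRNA hits it at
#' cryptogene scale in T-depleted space (or an rRNA hits in standard space);
#' MINICIRCLE_LIKE when it is not maxicircle-like, shares a conserved backbone
#' with other contigs and its length falls in the configured range; otherwise
#' UNCLASSIFIED. Circularity evidence is attached per contig.
#'
#' @param contigs named character vector of candidate mitochondrial contigs
#' @param mrna_set named character vector of mature mRNAs
#' @param rrna_set optional named character vector of rRNA transcripts
#' @param params an [mt_class_params()]
#' @return list with `classes` (data.frame: contig_id, label, n_evidence,
#'   evidence, circular, overlap_len, n_backbone), `backbones` (per-contig
#'   interval list from [find_backbone()]) and `evidence` (hit table)
#' @export
classify_contigs <- function(contigs, mrna_set, rrna_set = NULL,
                             params = mt_class_params()) {
  if (length(contigs) == 0) stop("empty contig set")
  ev_rows <- list()
  for (tid in names(mrna_set)) {
    h <- tdepleted_search(mrna_set[tid],
                          contigs,
                          search_params(seed_len = 10L,
                                        min_hit_len = params$maxi_min_hit,
                                        min_identity = params$maxi_min_identity,
                                        max_hits = 50L))
    if (nrow(h)) {
      h$evidence <- paste0("mrna:", tid)
      ev_rows[[length(ev_rows) + 1L]] <- h
    }
  }
  for (tid in names(rrna_set)) {
    h <- local_search(rrna_set[tid], contigs,
                      search_params(min_hit_len = params$rrna_min_hit,
                                    min_identity = params$rrna_min_identity,
                                    max_hits = 50L))
    if (nrow(h)) {
      h$evidence <- paste0("rrna:", tid)
      ev_rows[[length(ev_rows) + 1L]] <- h
    }
  }
  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    cbind(.empty_hits(), evidence = character(0))
  backbones <- if (length(contigs) >= 2L) {
    find_backbone(contigs, params$backbone_min_identity,
                  params$backbone_min_len, params$backbone_min_share)
  } else setNames(list(), character(0))
  rows <- lapply(names(contigs), function(cid) {
    ev <- unique(evidence$evidence[evidence$subject_id == cid])
    n <- nchar(contigs[[cid]])
    bb <- backbones[[cid]]
    nbb <- if (is.null(bb)) 0L else nrow(bb)
    label <- if (length(ev) > 0L) "MAXICIRCLE_LIKE"
    else if (nbb > 0L && n >= params$minicircle_len_range[1L] &&
             n <= params$minicircle_len_range[2L]) "MINICIRCLE_LIKE"
    else "UNCLASSIFIED"
    circ <- if (n > 2L * params$circ_min_overlap) {
      detect_circularity(contigs[cid], params$circ_min_overlap,
                         params$circ_max_mismatch)
    } else list(circular = FALSE, overlap_len = 0L)
    data.frame(contig_id = cid, label = label, n_evidence = length(ev),
               evidence = paste(ev, collapse = ","),
               circular = circ$circular, overlap_len = circ$overlap_len,
               n_backbone = nbb, stringsAsFactors = FALSE)
  })
  classes <- do.call(rbind, rows)
  rownames(classes) <- NULL
  list(classes = classes, backbones = backbones, evidence = evidence)
}
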
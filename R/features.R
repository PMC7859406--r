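#' @title Decontamination, transcript mapping and gene polarity
#' @description The prey-decontamination filter (flag assembly contigs highly
#'   similar to prey transcriptomes), unspliced transcript-to-genome mapping,
#'   and gene polarity/clustering statistics (same-strand fractions, strand
#'   runs, intergenic distances) for detecting polycistronic gene clusters.
#' @name genome_features
NULL

#' Decontamination parameters
#'
#' Defaults follow the empirical contaminant definition: >= 93% identity to a
#' prey contig over an alignment of >= 100 bp, both thresholds inclusive.
#' Identity is matches / alignment columns, gaps counting as columns.
#'
#' @param min_identity minimum identity (inclusive)
#' @param min_len minimum alignment length in columns (inclusive)
#' @return list of class `decontam_params`
#' @export
decontam_params <- function(min_identity = 0.93, min_len = 100L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_len >= 1)
  structure(list(min_identity = min_identity, min_len = as.integer(min_len)),
            class = "decontam_params")
}

#' Flag prey-contaminant contigs
#'
#' A contig is flagged iff ANY local alignment against the prey references
#' reaches `min_identity` over at least `min_len` alignment columns
#' (inclusive thresholds).
#'
#' @param contigs named character vector of assembly contigs
#' @param prey_refs named character vector of prey reference sequences
#' @param params a [decontam_params()]
#' @return data.frame: contig_id, flagged, best_identity, best_len,
#'   best_prey (NA when no hit at all)
#' @export
flag_prey_contigs <- function(contigs, prey_refs, params = decontam_params()) {
  if (length(prey_refs) == 0) stop("prey_refs must be non-empty")
  # short seeds: a segment at the 93% boundary can lack long exact words
  sp <- search_params(seed_len = 8L, min_hit_len = params$min_len,
                      min_identity = params$min_identity, max_hits = 10L)
  rows <- lapply(names(contigs), function(cid) {
    h <- local_search(contigs[cid], prey_refs, sp)
    # also look below threshold for reporting the best evidence
    if (nrow(h) == 0) {
      h <- local_search(contigs[cid], prey_refs,
                        search_params(seed_len = 8L, min_hit_len = 30L,
                                      min_identity = 0.5, max_hits = 1L))
    }
    qualifying <- nrow(h) > 0 &&
      any(h$identity >= params$min_identity &
            .aln_len(h) >= params$min_len)
    data.frame(contig_id = cid, flagged = qualifying,
               best_identity = if (nrow(h)) h$identity[[1L]] else NA_real_,
               best_len = if (nrow(h)) .aln_len(h)[[1L]] else NA_integer_,
               best_prey = if (nrow(h)) h$subject_id[[1L]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# alignment length in columns as reported by the search
.aln_len <- function(hits) hits$length

#' Map transcripts to genomic contigs
#'
#' Unspliced local mapping (no split alignments; consistent with the absence
#' of cis-introns in these genomes) keeping, per transcript and contig locus,
#' the best-scoring alignment at or above `min_identity`.
#'
#' @param transcripts named character vector
#' @param contigs named character vector
#' @param min_identity minimum identity (matches / alignment columns)
#' @param search base [search_params()] used for the scan
#' @return list with `mappings` (data.frame: transcript_id, contig_id,
#'   t_start, t_end, c_start, c_end, strand, identity, coverage) and
#'   `summary` (data.frame: n_transcripts, n_mapped, fraction_mapped)
#' @export
map_transcripts <- function(transcripts, contigs, min_identity = 0.90,
                            search = search_params()) {
  stopifnot(length(transcripts) > 0, length(contigs) > 0)
  search$min_identity <- min_identity
  rows <- list()
  for (tid in names(transcripts)) {
    h <- local_search(transcripts[tid], contigs, search)
    if (nrow(h) == 0) next
    # one best mapping per contig locus: drop lower-score hits overlapping a
    # kept hit on the same contig
    h <- h[order(-h$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(h))
    for (i in seq_len(nrow(h))[-1]) {
      for (j in which(keep[seq_len(i - 1L)])) {
        if (h$subject_id[i] == h$subject_id[j] &&
            min(h$s_end[i], h$s_end[j]) - max(h$s_start[i], h$s_start[j]) > 0) {
          keep[i] <- FALSE; break
        }
      }
    }
    h <- h[keep, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tid, contig_id = h$subject_id,
      t_start = h$q_start, t_end = h$q_end,
      c_start = h$s_start, c_end = h$s_end,
      strand = h$strand, identity = h$identity,
      coverage = (h$q_end - h$q_start) / nchar(transcripts[[tid]]),
      stringsAsFactors = FALSE)
  }
  mappings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), contig_id = character(0),
               t_start = integer(0), t_end = integer(0),
               c_start = integer(0), c_end = integer(0),
               strand = character(0), identity = numeric(0),
               coverage = numeric(0), stringsAsFactors = FALSE)
  rownames(mappings) <- NULL
  n_mapped <- length(unique(mappings$transcript_id))
  list(mappings = mappings,
       summary = data.frame(n_transcripts = length(transcripts),
                            n_mapped = n_mapped,
                            fraction_mapped = n_mapped / length(transcripts)))
}

#' Gene polarity and clustering report per contig
#'
#' Orders mapped genes along each contig and computes strand runs, the
#' same-strand (majority) fraction, and intergenic distances
#' (`next.start - prev.end`; overlapping mappings yield 0 with a flag).
#' Contigs with no mapped genes are omitted.
#'
#' @param mappings mapping data.frame from [map_transcripts()] (columns
#'   transcript_id, contig_id, c_start, c_end, strand)
#' @return list with `contigs` (data.frame: contig_id, n_genes,
#'   same_strand_fraction, strand_runs (comma string), n_intergenic,
#'   mean_intergenic, n_overlapping_flagged) and `intergenic` (data.frame:
#'   contig_id, left_gene, right_gene, distance, overlapping)
#' @export
polarity_report <- function(mappings) {
  if (is.null(mappings) || nrow(mappings) == 0) stop("no mappings supplied")
  per_contig <- split(mappings, mappings$contig_id)
  contig_rows <- list(); gap_rows <- list()
  for (cid in names(per_contig)) {
    g <- per_contig[[cid]]
    g <- g[order(g$c_start), , drop = FALSE]
    n <- nrow(g)
    runs <- rle(g$strand)$lengths
    ssf <- max(table(g$strand)) / n
    dist <- integer(0); overl <- logical(0)
    if (n > 1L) {
      raw <- g$c_start[-1L] - g$c_end[-n]
      overl <- raw < 0L
      dist <- pmax(raw, 0L)
      gap_rows[[length(gap_rows) + 1L]] <- data.frame(
        contig_id = cid,
        left_gene = g$transcript_id[-n], right_gene = g$transcript_id[-1L],
        distance = dist, overlapping = overl, stringsAsFactors = FALSE)
    }
    contig_rows[[length(contig_rows) + 1L]] <- data.frame(
      contig_id = cid, n_genes = n,
      same_strand_fraction = as.numeric(ssf),
      strand_runs = paste(runs, collapse = ","),
      n_intergenic = length(dist),
      mean_intergenic = if (length(dist)) mean(dist) else NA_real_,
      n_overlapping_flagged = sum(overl), stringsAsFactors = FALSE)
  }
  contigs <- do.call(rbind, contig_rows)
  intergenic <- if (length(gap_rows)) do.call(rbind, gap_rows) else
    data.frame(contig_id = character(0), left_gene = character(0),
               right_gene = character(0), distance = integer(0),
               overlapping = logical(0), stringsAsFactors = FALSE)
  rownames(contigs) <- NULL; rownames(intergenic) <- NULL
  list(contigs = contigs, intergenic = intergenic)
}

#' Export gene intervals as BED (0-based half-open)
#'
#' @param mappings mapping data.frame from [map_transcripts()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(mappings, path) {
  bed <- data.frame(chrom = mappings$contig_id, start = mappings$c_start,
                    end = mappings$c_end, name = mappings$transcript_id,
                    score = 0L, strand = mappings$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
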
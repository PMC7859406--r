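#' @title Editing statistics
#' @description Turn edit-event lists into per-transcript and species-level
#'   quantities: U-insertion/deletion counts, percent length expansion,
#'   editing-pattern class (pan vs terminal editing), deaminative-edit
#'   clusters, and stop-codon provenance.
#' @name editing_stats
NULL

.PATTERNS <- c("UNEDITED", "FIVE_PRIME", "FIVE_AND_THREE_PRIME", "PAN")

#' Classify the spatial editing pattern of a gene
#'
#' The aligned gene span is split into `n_bins` equal bins and a bin is
#' "edited" when it holds at least `density_min` edit sites (one site per
#' event run). Rules, in order: PAN when edited bins cover at least
#' `pan_frac` of bins; FIVE_PRIME when all edited bins fall in the first
#' `window_frac` of bins; FIVE_AND_THREE_PRIME when all edited bins fall in
#' the first or last `window_frac`; otherwise UNEDITED (which always applies
#' when there are fewer than 3 sites).
#'
#' @param events event data.frame (kind, gene_pos, mrna_pos, run_len)
#' @param gene_len length of the aligned gene span (> 0)
#' @param window_frac terminal fraction of bins regarded as 5'/3' regions
#' @param density_min minimum sites per bin for the bin to count as edited
#' @param gene_start 0-based start of the aligned span (event positions are
#'   absolute)
#' @param n_bins number of bins
#' @param pan_frac minimum edited-bin fraction for PAN
#' @return one of `"UNEDITED"`, `"FIVE_PRIME"`, `"FIVE_AND_THREE_PRIME"`,
#'   `"PAN"`
#' @export
classify_pattern <- function(events, gene_len, window_frac = 0.25,
                             density_min = 1, gene_start = 0L,
                             n_bins = 20L, pan_frac = 0.70) {
  if (gene_len <= 0) stop("gene_len must be > 0")
  if (is.null(events) || nrow(events) < 3L) return("UNEDITED")
  rel <- (events$gene_pos - gene_start) / gene_len
  rel <- pmin(pmax(rel, 0), 1 - 1e-9)
  bin <- floor(rel * n_bins)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  edited <- which(counts >= density_min) - 1L
  if (length(edited) == 0) return("UNEDITED")
  head_bins <- 0:(ceiling(window_frac * n_bins) - 1L)
  tail_bins <- (n_bins - ceiling(window_frac * n_bins)):(n_bins - 1L)
  if (length(edited) / n_bins >= pan_frac) return("PAN")
  if (all(edited %in% head_bins)) return("FIVE_PRIME")
  if (all(edited %in% c(head_bins, tail_bins))) return("FIVE_AND_THREE_PRIME")
  "UNEDITED"
}

#' Per-transcript editing statistics from an alignment
#'
#' @param aln an `editing_alignment` from [align_editing()]
#' @param code genetic code id for stop-codon provenance (default "4", the
#'   kinetoplastid mitochondrial code where TGA encodes Trp)
#' @param frame_start 0-based reading-frame offset on the mRNA
#' @param ... passed to [classify_pattern()]
#' @return one-row data.frame: gene_id, mrna_id, gene_len, n_ins, n_del,
#'   pct_expansion (exactly `100 * (n_ins - n_del) / gene_len`), n_c_to_u,
#'   n_a_to_i, pattern, stop_created_by_editing
#' @export
summarize_editing <- function(aln, code = "4", frame_start = 0L, ...) {
  stopifnot(inherits(aln, "editing_alignment"))
  if (isTRUE(aln$unalignable)) stop("cannot summarize an unalignable alignment")
  gene_len <- aln$gene_ival$end - aln$gene_ival$start
  if (gene_len == 0) stop("gene length is zero")
  ev <- aln$events
  n_ins <- aln$n_ins; n_del <- aln$n_del
  data.frame(
    gene_id = aln$gene_id, mrna_id = aln$mrna_id,
    gene_len = gene_len, n_ins = n_ins, n_del = n_del,
    pct_expansion = 100 * (n_ins - n_del) / gene_len,
    n_c_to_u = sum(ev$kind == "C_TO_U"),
    n_a_to_i = sum(ev$kind == "A_TO_I"),
    pattern = classify_pattern(ev, gene_len, gene_start = aln$gene_ival$start, ...),
    stop_created_by_editing = stop_created_by_editing(aln, code = code,
                                                      frame_start = frame_start),
    stringsAsFactors = FALSE)
}

#' Detect clusters of deaminative (C-to-U / A-to-I) edits
#'
#' Maximal groups of substitution events in which consecutive edits lie at
#' most `window` nt apart on the gene, with at least `min_edits` members.
#' Spans are tight (first to last edit site).
#'
#' @param events event data.frame
#' @param window maximum gap between consecutive clustered edits (nt)
#' @param min_edits minimum cluster size
#' @param seq_id id recorded in the cluster table
#' @return data.frame: seq_id, start, end (0-based half-open tight span),
#'   n_edits, n_c_to_u, n_a_to_i
#' @export
detect_deaminative_clusters <- function(events, window = 30L, min_edits = 3L,
                                        seq_id = "gene") {
  stopifnot(window >= 1)
  empty <- data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      n_edits = integer(0), n_c_to_u = integer(0),
                      n_a_to_i = integer(0), stringsAsFactors = FALSE)
  subs <- events[events$kind %in% c("C_TO_U", "A_TO_I"), , drop = FALSE]
  if (nrow(subs) == 0) return(empty)
  subs <- subs[order(subs$gene_pos), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(diff(subs$gene_pos) > window)))
  rows <- lapply(split(subs, grp), function(g) {
    if (nrow(g) < min_edits) return(NULL)
    data.frame(seq_id = seq_id,
               start = min(g$gene_pos), end = max(g$gene_pos) + 1L,
               n_edits = nrow(g),
               n_c_to_u = sum(g$kind == "C_TO_U"),
               n_a_to_i = sum(g$kind == "A_TO_I"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Was the first in-frame stop codon created by U-indel editing?
#'
#' Translates the edited mRNA in the given frame under the given genetic code
#' and reports TRUE when the first in-frame stop codon overlaps at least one
#' inserted-U position, or a U deletion junction falls within the codon.
#'
#' @param aln an `editing_alignment`
#' @param code NCBI genetic code id (default "4": TGA = Trp, the mitochondrial
#'   code used by kinetoplastids)
#' @param frame_start 0-based frame offset on the mRNA
#' @return logical flag; FALSE with a warning when no in-frame stop exists
#' @export
stop_created_by_editing <- function(aln, code = "4", frame_start = 0L) {
  stopifnot(inherits(aln, "editing_alignment"))
  if (isTRUE(aln$unalignable)) return(NA)
  mrna <- gsub("-", "", aln$mrna_row, fixed = TRUE)
  if (nchar(mrna) < frame_start + 3L) stop("mRNA shorter than frame_start + 3")
  gcode <- tryCatch(Biostrings::getGeneticCode(as.character(code)),
                    error = function(e) stop("unknown genetic code id: ", code))
  cds <- substr(mrna, frame_start + 1L, nchar(mrna))
  ncod <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
  aa <- gcode[codons]
  aa[is.na(aa)] <- "X"
  stop_i <- which(aa == "*")
  if (!length(stop_i)) {
    warning("no in-frame stop codon under genetic code ", code,
            " for ", aln$mrna_id)
    return(FALSE)
  }
  s <- frame_start + 3L * (stop_i[[1L]] - 1L)  # 0-based codon start on mRNA
  ev <- aln$events
  ins <- ev[ev$kind == "U_INS", , drop = FALSE]
  if (nrow(ins)) {
    ovl <- ins$mrna_pos < (s + 3L) & (ins$mrna_pos + ins$run_len) > s
    if (any(ovl)) return(TRUE)
  }
  del <- ev[ev$kind == "U_DEL", , drop = FALSE]
  if (nrow(del) && any(del$mrna_pos >= s & del$mrna_pos <= s + 3L)) return(TRUE)
  FALSE
}

#' Species-level summary over per-gene editing statistics
#'
#' @param stats data.frame of per-gene rows from [summarize_editing()]
#' @return one-row data.frame: n_genes, mean/min/max of n_ins, n_del and
#'   pct_expansion
#' @export
aggregate_editing <- function(stats) {
  if (is.null(stats) || nrow(stats) == 0) stop("empty stats table")
  data.frame(
    n_genes = nrow(stats),
    mean_ins = mean(stats$n_ins), min_ins = min(stats$n_ins), max_ins = max(stats$n_ins),
    mean_del = mean(stats$n_del), min_del = min(stats$n_del), max_del = max(stats$n_del),
    mean_pct_expansion = mean(stats$pct_expansion),
    min_pct_expansion = min(stats$pct_expansion),
    max_pct_expansion = max(stats$pct_expansion))
}

#' Per-gene editing-density profile
#'
#' Site counts per equal-width bin along the aligned gene span, for plotting
#' editing-density profiles.
#'
#' @param aln an `editing_alignment`
#' @param n_bins number of bins
#' @return data.frame: gene_id, bin (0-based), n_sites
#' @export
editing_profile <- function(aln, n_bins = 20L) {
  stopifnot(inherits(aln, "editing_alignment"), !isTRUE(aln$unalignable))
  gene_len <- aln$gene_ival$end - aln$gene_ival$start
  rel <- (aln$events$gene_pos - aln$gene_ival$start) / gene_len
  rel <- pmin(pmax(rel, 0), 1 - 1e-9)
  counts <- tabulate(floor(rel * n_bins) + 1L, nbins = n_bins)
  data.frame(gene_id = aln$gene_id, bin = 0:(n_bins - 1L), n_sites = counts,
             stringsAsFactors = FALSE)
}
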
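#' @title Synthetic prokinetoplastid data with ground truth
#' @description Seeded generator emulating the statistical structure the other
#'   modules assume: maxicircle contigs carrying cryptogenes of U-indel edited
#'   mRNAs (a shared conserved backbone plus genes whose transcripts are
#'   expanded by U insertions), minicircles with a conserved backbone plus
#'   ~85 bp gRNA cassettes antisense (with G:U wobble) to edited mRNA blocks,
#'   nuclear contigs with same-strand gene clusters and small intergenic
#'   distances, SL-bearing transcripts at a stated fraction, and prey-like
#'   contaminant segments at controlled identity. Every simulated quantity is
#'   recorded in truth tables enabling exact parameter-recovery tests.
#' @name simulate
NULL

#' Random DNA of a given length and GC content
#' @param n length
#' @param gc GC fraction
#' @return character scalar
#' @export
random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

#' Simulation parameters
#'
#' Presets describe two prokinetoplastid editing regimes: "ankaliazontas"-like (pan-editing
#' dominant; U insertions mean 389, range 166-885; deletions mean 29, range
#' 13-49; one deaminative cluster of 8 C-to-U + 4 A-to-I edits over 30 nt in
#' an rRNA-like gene; minicircles 1300-2200 bp with 2 cassettes, circular)
#' and "spiralis"-like (terminal editing dominant; insertions mean 166, range
#' 19-331; deletions mean 43, range 17-80; ~600 bp minicircles with a single
#' ~85 bp cassette, linear). Any field can be overridden via `...`.
#'
#' @param preset "ankaliazontas" or "spiralis"
#' @param seed integer seed; identical parameters (incl. seed) give
#'   byte-identical outputs
#' @param ... named overrides of any parameter field
#' @return list of class `sim_params`
#' @export
sim_params <- function(preset = c("ankaliazontas", "spiralis"), seed = 1L, ...) {
  preset <- match.arg(preset)
  p <- list(
    preset = preset, seed = as.integer(seed),
    n_genes = 14L,
    gene_len_range = c(400L, 1200L),
    ins_per_gene = c(mean = 389, min = 166, max = 885),
    del_per_gene = c(mean = 29, min = 13, max = 49),
    ins_run_geom_p = 0.5, max_run_len = 6L,
    pattern_mix = c(PAN = 0.85, FIVE_PRIME = 0, FIVE_AND_THREE_PRIME = 0.15,
                    UNEDITED = 0),
    deam_cluster = c(n_c_to_u = 8L, n_a_to_i = 4L, span = 30L),
    rrna_len = 600L,
    genes_per_maxicircle = 3L, maxi_backbone_len = 400L,
    maxi_spacer_len = 100L, maxicircle_circular = TRUE,
    terminal_dup_len = 120L,
    n_minicircles = 10L, minicircle_len_range = c(1300L, 2200L),
    cassettes_per_minicircle = 2L, cassette_len = 85L,
    wobble_frac = 0.05, backbone_mut_rate = 0.02,
    minicircle_circular = TRUE,
    n_nuclear_genes = 30L, genes_per_contig = 10L,
    nuclear_gene_len_range = c(300L, 1200L),
    intergenic_mean = 76L, intergenic_mode = "geometric",
    nuclear_flank_len = 200L, n_unplaced_transcripts = 0L,
    sl_fraction = 0.70, sl_seq = "TTACAGTTTCTGTACTT",
    prey = c(n_contigs = 4, identity = 0.95, seg_len = 120),
    n_contaminated = 1L,
    gc = 0.5)
  if (preset == "spiralis") {
    p$n_genes <- 12L
    p$ins_per_gene <- c(mean = 166, min = 19, max = 331)
    p$del_per_gene <- c(mean = 43, min = 17, max = 80)
    p$pattern_mix <- c(PAN = 0.3, FIVE_PRIME = 0.3,
                       FIVE_AND_THREE_PRIME = 0.4, UNEDITED = 0)
    p$deam_cluster <- NULL
    p$minicircle_len_range <- c(550L, 650L)
    p$cassettes_per_minicircle <- 1L
    p$minicircle_circular <- FALSE
    p$maxicircle_circular <- FALSE
    p$sl_fraction <- 0.58
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown sim_params field(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "sim_params")
}

# allowed edit positions (0-based) for a pattern class; the outer `margin`
# positions are kept edit-free so alignments anchor at gene ends
.pattern_region <- function(pattern, len, margin = 5L) {
  lo <- margin; hi <- len - margin - 1L
  switch(pattern,
         PAN = lo:hi,
         FIVE_PRIME = lo:max(lo, floor(0.24 * len)),
         FIVE_AND_THREE_PRIME = c(lo:max(lo, floor(0.24 * len)),
                                  min(hi, ceiling(0.76 * len)):hi),
         UNEDITED = integer(0))
}

# greedy selection of positions with pairwise distance >= min_dist, keeping
# exclude_dist away from already-fixed positions
.pick_spaced <- function(candidates, n, min_dist = 3L, exclude = integer(0),
                         exclude_dist = min_dist) {
  cand <- sample(candidates)
  picked <- integer(0)
  for (p in cand) {
    if (length(picked) >= n) break
    if (length(exclude) && any(abs(exclude - p) < exclude_dist)) next
    if (length(picked) && any(abs(picked - p) < min_dist)) next
    picked <- c(picked, p)
  }
  sort(picked)
}

# sample one edited gene: returns gene seq, mRNA seq, canonical truth events
.sim_gene <- function(gid, params) {
  len <- sample(params$gene_len_range[1L]:params$gene_len_range[2L], 1L)
  gene <- random_dna(len, params$gc)
  gc_chars <- strsplit(gene, "", fixed = TRUE)[[1L]]
  pattern <- sample(names(params$pattern_mix), 1L, prob = params$pattern_mix)
  region <- .pattern_region(pattern, len)
  draw <- function(spec) {
    max(spec[["min"]],
        min(spec[["max"]],
            round(stats::rnorm(1, spec[["mean"]],
                               (spec[["max"]] - spec[["min"]]) / 6))))
  }
  n_ins_target <- if (pattern == "UNEDITED") 0L else draw(params$ins_per_gene)
  n_del_target <- if (pattern == "UNEDITED") 0L else draw(params$del_per_gene)
  # deletions first (their candidate pool - gene T-runs - is the scarcer one):
  # k <= run-length U's are deleted from the start of a maximal T-run, which
  # is the canonical (leftmost) placement; runs are kept >= 3 nt apart
  in_region <- logical(len); in_region[region + 1L] <- TRUE
  r <- rle(gc_chars == "T")
  r_end <- cumsum(r$lengths); r_start <- r_end - r$lengths + 1L
  t_runs <- data.frame(start = r_start[r$values], end = r_end[r$values])
  ok_run <- vapply(seq_len(nrow(t_runs)), function(i) {
    all(in_region[t_runs$start[i]:t_runs$end[i]])
  }, logical(1))
  t_runs <- t_runs[ok_run, , drop = FALSE]
  if (n_del_target > 0L && nrow(t_runs) == 0L) {
    stop("infeasible params: no T available for deletions in gene ", gid)
  }
  del_pos <- integer(0); del_lens <- integer(0)
  if (n_del_target > 0L && nrow(t_runs)) {
    ord <- sample(nrow(t_runs))
    sel <- integer(0)
    for (i in ord) {
      if (length(sel) &&
          any(pmax(t_runs$start[sel], t_runs$start[i]) -
                pmin(t_runs$end[sel], t_runs$end[i]) < 3L)) next
      sel <- c(sel, i)
      if (length(sel) >= n_del_target) break
    }
    caps <- t_runs$end[sel] - t_runs$start[sel] + 1L
    assigned <- pmin(1L, caps)
    while (sum(assigned) < n_del_target && any(assigned < caps)) {
      j <- which(assigned < caps)[1L]
      assigned[j] <- assigned[j] + 1L
    }
    keep <- assigned > 0L
    del_pos <- t_runs$start[sel][keep] - 1L   # 0-based run starts
    del_lens <- assigned[keep]
    o <- order(del_pos)
    del_pos <- del_pos[o]; del_lens <- del_lens[o]
  }
  del_excl <- if (length(del_pos)) {
    unlist(mapply(function(p, l) seq(p - 2L, p + l + 1L), del_pos, del_lens,
                  SIMPLIFY = FALSE))
  } else integer(0)
  # insertion run positions: before a gene position whose predecessor is not T
  # (so the planted placement is already canonical / leftmost), and not
  # adjacent to a deletion (adjacency would let the aligner cancel the pair)
  ins_cand <- region[region >= 1L & gc_chars[region] != "T"]
  run_lens <- integer(0)
  if (n_ins_target > 0L) {
    while (sum(run_lens) < n_ins_target) {
      run_lens <- c(run_lens,
                    as.integer(min(params$max_run_len,
                                   1L + stats::rgeom(1, params$ins_run_geom_p))))
    }
    over <- sum(run_lens) - n_ins_target
    if (over > 0L) run_lens[length(run_lens)] <- run_lens[length(run_lens)] - over
    run_lens <- run_lens[run_lens > 0L]
  }
  ins_pos <- .pick_spaced(ins_cand, length(run_lens), min_dist = 2L,
                          exclude = del_excl, exclude_dist = 1L)
  if (length(ins_pos) < length(run_lens)) {
    # fewer slots than runs: redistribute the unplaced U's onto placed runs
    surplus <- sum(run_lens[-seq_along(ins_pos)])
    run_lens <- run_lens[seq_along(ins_pos)]
    while (surplus > 0L && any(run_lens < params$max_run_len)) {
      i <- which.min(run_lens)
      run_lens[i] <- run_lens[i] + 1L
      surplus <- surplus - 1L
    }
  }
  events <- rbind(
    if (length(ins_pos)) data.frame(kind = "U_INS", gene_pos = ins_pos,
                                    mrna_pos = NA_integer_, run_len = run_lens,
                                    stringsAsFactors = FALSE),
    if (length(del_pos)) data.frame(kind = "U_DEL", gene_pos = del_pos,
                                    mrna_pos = NA_integer_, run_len = del_lens,
                                    stringsAsFactors = FALSE))
  if (is.null(events)) events <- .empty_events()
  events <- events[order(events$gene_pos), , drop = FALSE]
  # fill in mRNA positions by walking the gene
  if (nrow(events)) {
    shift <- 0L
    for (r in seq_len(nrow(events))) {
      events$mrna_pos[r] <- events$gene_pos[r] + shift
      if (events$kind[r] == "U_INS") shift <- shift + events$run_len[r]
      else shift <- shift - events$run_len[r]
    }
  }
  rownames(events) <- NULL
  mrna <- apply_edit_events(gene, events)
  list(gene_id = gid, gene = gene, mrna = mrna, events = events,
       pattern = pattern, gene_len = len,
       n_ins = as.integer(sum(events$run_len[events$kind == "U_INS"])),
       n_del = as.integer(sum(events$run_len[events$kind == "U_DEL"])))
}

# rRNA-like gene: no U indels; optional deaminative cluster and a planted
# stem-loop (for motif-search demonstrations)
.sim_rrna <- function(params) {
  len <- params$rrna_len
  gene <- random_dna(len, params$gc)
  gc_chars <- strsplit(gene, "", fixed = TRUE)[[1L]]
  # plant a hairpin: 6 bp stem, GAAA tetraloop
  stem5 <- "GGCAGC"; loop <- "GAAA"
  hp <- paste0(stem5, loop, revcomp(stem5))
  hp_at <- 50L  # 0-based
  gc_chars[(hp_at + 1L):(hp_at + nchar(hp))] <- strsplit(hp, "")[[1L]]
  events <- .empty_events()
  if (!is.null(params$deam_cluster)) {
    dc <- params$deam_cluster
    n_ed <- dc[["n_c_to_u"]] + dc[["n_a_to_i"]]
    w0 <- floor(len / 2)  # 0-based cluster window start
    pos <- sort(sample(0:(dc[["span"]] - 1L), n_ed)) + w0
    kind <- sample(rep(c("C_TO_U", "A_TO_I"),
                       c(dc[["n_c_to_u"]], dc[["n_a_to_i"]])))
    gc_chars[pos + 1L] <- ifelse(kind == "C_TO_U", "C", "A")
    events <- data.frame(kind = kind, gene_pos = pos, mrna_pos = pos,
                         run_len = 1L, stringsAsFactors = FALSE)
    events <- events[order(events$gene_pos), , drop = FALSE]
    rownames(events) <- NULL
  }
  gene <- paste0(gc_chars, collapse = "")
  mrna <- apply_edit_events(gene, events)
  list(gene_id = "rRNA12S", gene = gene, mrna = mrna, events = events,
       pattern = "UNEDITED", gene_len = len,
       n_ins = 0L, n_del = 0L, hairpin_at = hp_at, hairpin = hp)
}

.mutate_seq <- function(seq, rate, exact = FALSE) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- if (exact) {
    sample(seq_along(ch), round(rate * length(ch)))
  } else {
    which(stats::runif(length(ch)) < rate)
  }
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste0(ch, collapse = "")
}

#' Simulate the mitochondrial compartment
#'
#' Genes are drawn, mature mRNAs derived by applying sampled U-indel (and, for
#' the rRNA-like gene, deaminative) edit events, maxicircles assembled as a
#' shared backbone plus cryptogenes on random strands, and minicircles as a
#' shared (lightly mutated) backbone carrying gRNA cassettes that are
#' wobble-perturbed reverse complements of edited-mRNA blocks. Applying each
#' gene's truth events to its cryptogene reproduces its mature mRNA exactly.
#'
#' @param params a [sim_params()]
#' @return list: `maxicircles`, `minicircles`, `mrnas` (mature mt mRNAs),
#'   `rrnas`, and `truth` (gene table, canonical edit events in both gene-local
#'   and contig coordinates, gene intervals on maxicircles, cassette table)
#' @export
simulate_mt <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  genes <- lapply(seq_len(params$n_genes),
                  function(i) .sim_gene(sprintf("mtgene%02d", i), params))
  rrna <- if (!is.null(params$deam_cluster)) .sim_rrna(params) else NULL
  all_genes <- c(genes, if (!is.null(rrna)) list(rrna))

  # --- maxicircles: shared backbone + genes on random strands
  backbone <- random_dna(params$maxi_backbone_len, params$gc)
  groups <- split(seq_along(all_genes),
                  ceiling(seq_along(all_genes) / params$genes_per_maxicircle))
  maxis <- character(0); gene_iv_rows <- list()
  for (k in seq_along(groups)) {
    cid <- sprintf("maxi%02d", k)
    parts <- c(backbone)
    pos <- nchar(backbone)
    for (gi in groups[[k]]) {
      spacer <- random_dna(params$maxi_spacer_len, params$gc)
      g <- all_genes[[gi]]
      strand <- sample(c("+", "-"), 1L)
      emb <- if (strand == "+") g$gene else revcomp(g$gene)
      parts <- c(parts, spacer, emb)
      start <- pos + params$maxi_spacer_len
      gene_iv_rows[[length(gene_iv_rows) + 1L]] <- data.frame(
        contig_id = cid, gene_id = g$gene_id, start = start,
        end = start + g$gene_len, strand = strand,
        class = if (g$gene_id == "rRNA12S") "rRNA" else "mRNA",
        stringsAsFactors = FALSE)
      pos <- start + g$gene_len
    }
    parts <- c(parts, random_dna(params$maxi_spacer_len, params$gc))
    contig <- paste0(parts, collapse = "")
    if (params$maxicircle_circular) {
      contig <- paste0(contig, substr(contig, 1L, params$terminal_dup_len))
    }
    maxis[cid] <- contig
  }

  mrnas <- setNames(vapply(genes, `[[`, "", "mrna"),
                    vapply(genes, `[[`, "", "gene_id"))
  rrnas <- if (!is.null(rrna)) setNames(rrna$mrna, rrna$gene_id) else
    setNames(character(0), character(0))

  # --- minicircles: shared backbone prefix + antisense cassettes
  mini_backbone <- random_dna(max(params$minicircle_len_range) -
                                params$cassettes_per_minicircle * params$cassette_len,
                              params$gc)
  minis <- character(0); cassette_rows <- list()
  for (k in seq_len(params$n_minicircles)) {
    cid <- sprintf("mini%02d", k)
    len <- sample(params$minicircle_len_range[1L]:params$minicircle_len_range[2L], 1L)
    bb_len <- len - params$cassettes_per_minicircle * params$cassette_len
    bb <- .mutate_seq(substr(mini_backbone, 1L, bb_len), params$backbone_mut_rate)
    # cassette cut points in backbone coordinates; assembled by splitting the
    # backbone so each cassette's final position is cut + (#cassettes before)*len
    cuts <- sort(.pick_spaced(seq(20L, bb_len - 20L),
                              params$cassettes_per_minicircle, min_dist = 30L))
    contig <- bb
    n_before <- 0L
    for (cut in cuts) {
      o <- cut + n_before * params$cassette_len  # position in current contig
      tid <- sample(names(mrnas), 1L)
      M <- nchar(mrnas[[tid]])
      b0 <- sample(0:(M - params$cassette_len), 1L)  # 0-based block start
      block <- substr(mrnas[[tid]], b0 + 1L, b0 + params$cassette_len)
      gr <- revcomp(block)  # perfect antisense gRNA
      grc <- strsplit(gr, "", fixed = TRUE)[[1L]]
      blc <- strsplit(block, "", fixed = TRUE)[[1L]]
      # wobble conversions: at mRNA T make gRNA G; at mRNA G make gRNA T
      elig <- which(blc %in% c("T", "G"))
      n_wob <- round(params$wobble_frac * params$cassette_len)
      wob <- if (length(elig) && n_wob > 0L) {
        sample(elig, min(n_wob, length(elig)))
      } else integer(0)
      for (i in wob) {
        j <- params$cassette_len - i + 1L  # revcomp position pairing block[i]
        grc[j] <- if (blc[i] == "T") "G" else "T"
      }
      gr <- paste0(grc, collapse = "")
      strand <- sample(c("+", "-"), 1L)
      emb <- if (strand == "+") gr else revcomp(gr)
      contig <- paste0(substr(contig, 1L, o),
                       emb,
                       substr(contig, o + 1L, nchar(contig)))
      cassette_rows[[length(cassette_rows) + 1L]] <- data.frame(
        minicircle_id = cid, cassette_start = o,
        cassette_end = o + params$cassette_len, strand = strand,
        mrna_id = tid, mrna_start = b0, mrna_end = b0 + params$cassette_len,
        n_wobble = length(wob), stringsAsFactors = FALSE)
      n_before <- n_before + 1L
    }
    if (params$minicircle_circular) {
      contig <- paste0(contig, substr(contig, 1L, params$terminal_dup_len))
    }
    minis[cid] <- contig
  }

  gene_truth <- do.call(rbind, lapply(all_genes, function(g) {
    data.frame(gene_id = g$gene_id, gene_len = g$gene_len,
               n_ins = g$n_ins, n_del = g$n_del,
               pct_expansion = 100 * (g$n_ins - g$n_del) / g$gene_len,
               pattern = g$pattern,
               class = if (g$gene_id == "rRNA12S") "rRNA" else "mRNA",
               stringsAsFactors = FALSE)
  }))
  events_truth <- do.call(rbind, lapply(all_genes, function(g) {
    if (nrow(g$events) == 0) return(NULL)
    cbind(gene_id = g$gene_id, g$events, stringsAsFactors = FALSE)
  }))
  gene_seqs <- setNames(vapply(all_genes, `[[`, "", "gene"),
                        vapply(all_genes, `[[`, "", "gene_id"))
  list(maxicircles = maxis, minicircles = minis, mrnas = mrnas, rrnas = rrnas,
       gene_seqs = gene_seqs,
       truth = list(genes = gene_truth,
                    events = events_truth,
                    gene_intervals = do.call(rbind, gene_iv_rows),
                    cassettes = do.call(rbind, cassette_rows),
                    rrna_hairpin = if (!is.null(rrna)) {
                      data.frame(gene_id = rrna$gene_id, start = rrna$hairpin_at,
                                 end = rrna$hairpin_at + nchar(rrna$hairpin),
                                 seq = rrna$hairpin, stringsAsFactors = FALSE)
                    } else NULL),
       params = params)
}

#' Simulate the nuclear compartment
#'
#' Contigs carry same-strand gene clusters (one strand per contig) separated
#' by small intergenic gaps (geometric around `intergenic_mean`, or constant
#' when `intergenic_mode = "fixed"`). One transcript is emitted per gene, plus
#' optional unplaced transcripts with no genomic locus; a Bernoulli
#' (`sl_fraction`) subset of all transcripts receives the SL prefix.
#'
#' @param params a [sim_params()]
#' @return list: `contigs`, `transcripts`, `truth` (gene intervals/strands,
#'   SL-bearing transcript ids, placement status)
#' @export
simulate_nuclear <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  n <- params$n_nuclear_genes
  contigs <- character(0)
  gene_rows <- list(); transcripts <- character(0)
  gi <- 0L
  n_contigs <- ceiling(n / params$genes_per_contig)
  for (k in seq_len(n_contigs)) {
    cid <- sprintf("nuc%03d", k)
    n_here <- min(params$genes_per_contig, n - gi)
    strand <- sample(c("+", "-"), 1L)
    parts <- random_dna(params$nuclear_flank_len, params$gc)
    pos <- params$nuclear_flank_len
    for (j in seq_len(n_here)) {
      gi <- gi + 1L
      gid <- sprintf("ngene%04d", gi)
      glen <- sample(params$nuclear_gene_len_range[1L]:params$nuclear_gene_len_range[2L], 1L)
      gene <- random_dna(glen, params$gc)
      if (j > 1L) {
        gap <- if (identical(params$intergenic_mode, "fixed")) {
          params$intergenic_mean
        } else {
          stats::rgeom(1L, 1 / (params$intergenic_mean + 1))
        }
        if (gap > 0L) {
          parts <- c(parts, random_dna(gap, params$gc))
          pos <- pos + gap
        }
      }
      emb <- if (strand == "+") gene else revcomp(gene)
      parts <- c(parts, emb)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        contig_id = cid, gene_id = gid, start = pos, end = pos + glen,
        strand = strand, stringsAsFactors = FALSE)
      transcripts[gid] <- gene
      pos <- pos + glen
    }
    parts <- c(parts, random_dna(params$nuclear_flank_len, params$gc))
    contigs[cid] <- paste0(parts, collapse = "")
  }
  placed <- names(transcripts)
  if (params$n_unplaced_transcripts > 0L) {
    for (j in seq_len(params$n_unplaced_transcripts)) {
      gid <- sprintf("orphan%04d", j)
      transcripts[gid] <- random_dna(
        sample(params$nuclear_gene_len_range[1L]:params$nuclear_gene_len_range[2L], 1L),
        params$gc)
    }
  }
  has_sl <- stats::rbinom(length(transcripts), 1L, params$sl_fraction) == 1L
  sl_ids <- names(transcripts)[has_sl]
  transcripts[has_sl] <- paste0(params$sl_seq, transcripts[has_sl])
  list(contigs = contigs, transcripts = transcripts,
       truth = list(genes = do.call(rbind, gene_rows),
                    sl_ids = sl_ids,
                    placed_ids = placed),
       params = params)
}

#' Simulate prey contamination
#'
#' Generates prey reference contigs and embeds, into a subset of target
#' contigs, a prey segment copied at the configured per-base identity and
#' length; contaminated contig ids are recorded as truth.
#'
#' @param params a [sim_params()]
#' @param target_contigs named character vector to contaminate (a copy is
#'   returned; input is not modified)
#' @return list: `prey` (reference contigs), `contigs` (target contigs with
#'   contamination applied), `truth` (contaminated ids + segment provenance)
#' @export
simulate_contamination <- function(params, target_contigs) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 2L)
  pr <- params$prey
  identity <- pr[["identity"]]
  stopifnot(identity > 0, identity <= 1)
  seg_len <- as.integer(pr[["seg_len"]])
  prey <- setNames(
    vapply(seq_len(pr[["n_contigs"]]),
           function(i) random_dna(sample(1500:2500, 1L), params$gc), ""),
    sprintf("prey%02d", seq_len(pr[["n_contigs"]])))
  n_cont <- min(params$n_contaminated, length(target_contigs))
  victims <- sample(names(target_contigs), n_cont)
  rows <- list()
  out <- target_contigs
  for (cid in victims) {
    pid <- sample(names(prey), 1L)
    pL <- nchar(prey[[pid]])
    p0 <- sample(0:(pL - seg_len), 1L)
    seg <- substr(prey[[pid]], p0 + 1L, p0 + seg_len)
    seg <- .mutate_seq(seg, 1 - identity, exact = TRUE)  # identity is exact
    at <- nchar(out[[cid]])
    out[cid] <- paste0(out[[cid]], random_dna(30L, params$gc), seg,
                       random_dna(30L, params$gc))
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = cid, prey_id = pid, prey_start = p0,
      contig_start = at + 30L, seg_len = seg_len, stringsAsFactors = FALSE)
  }
  list(prey = prey, contigs = out,
       truth = list(contaminated_ids = victims,
                    segments = if (length(rows)) do.call(rbind, rows) else NULL))
}

#' Simulate a full study-like bundle (mitochondrial + nuclear + contamination)
#'
#' @param params a [sim_params()]
#' @return list of class `sim_bundle` with elements `mt`, `nuclear`, `contam`
#'   and convenience top-level sets: `mt_contigs` (maxicircles + minicircles),
#'   `mrnas`, `rrnas`, `nuclear_contigs` (contaminated), `transcripts`,
#'   `prey`, `sl_refs`
#' @export
simulate_bundle <- function(params = sim_params()) {
  mt <- simulate_mt(params)
  nuc <- simulate_nuclear(params)
  contam <- simulate_contamination(params, nuc$contigs)
  refs <- sl_refs(name = "SL_target", seq = params$sl_seq, source = "TARGET")
  structure(list(mt = mt, nuclear = nuc, contam = contam,
                 mt_contigs = c(mt$maxicircles, mt$minicircles),
                 mrnas = mt$mrnas, rrnas = mt$rrnas,
                 nuclear_contigs = contam$contigs,
                 transcripts = nuc$transcripts,
                 prey = contam$prey, sl_refs = refs,
                 params = params),
            class = "sim_bundle")
}

#' Write a simulated bundle to disk (FASTA + truth TSV + params)
#'
#' @param bundle a `sim_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$mt_contigs, file.path(dir, "mt_contigs.fasta"))
  write_fasta(bundle$mrnas, file.path(dir, "mt_mrnas.fasta"))
  if (length(bundle$rrnas)) write_fasta(bundle$rrnas, file.path(dir, "mt_rrnas.fasta"))
  write_fasta(bundle$nuclear_contigs, file.path(dir, "nuclear_contigs.fasta"))
  write_fasta(bundle$transcripts, file.path(dir, "transcripts.fasta"))
  write_fasta(bundle$prey, file.path(dir, "prey.fasta"))
  write_fasta(setNames(bundle$sl_refs$seq, bundle$sl_refs$name),
              file.path(dir, "sl_refs.fasta"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_table(bundle$mt$truth$genes, file.path(tdir, "mt_genes.tsv"))
  write_table(bundle$mt$truth$events, file.path(tdir, "mt_events.tsv"))
  write_table(bundle$mt$truth$gene_intervals, file.path(tdir, "mt_gene_intervals.tsv"))
  write_table(bundle$mt$truth$cassettes, file.path(tdir, "cassettes.tsv"))
  write_table(bundle$nuclear$truth$genes, file.path(tdir, "nuclear_genes.tsv"))
  writeLines(bundle$nuclear$truth$sl_ids, file.path(tdir, "sl_ids.txt"))
  writeLines(bundle$contam$truth$contaminated_ids,
             file.path(tdir, "contaminated_ids.txt"))
  p <- bundle$params
  yaml::write_yaml(unclass(p), file.path(dir, "sim_params.yaml"))
  invisible(dir)
}
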
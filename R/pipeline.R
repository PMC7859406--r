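#' @title End-to-end pipeline
#' @description Orchestrates the full analysis from a single configuration:
#'   decontaminate -> classify mitochondrial contigs -> locate cryptogenes ->
#'   reconstruct editing -> editing statistics -> gRNA detection -> SL
#'   detection -> transcript mapping and polarity. All stage outputs are TSV
#'   (plus FASTA for extracted regions) in the configured output directory;
#'   a manifest records parameters and input checksums. Outputs are pure
#'   functions of (inputs, config): re-running reproduces identical bytes.
#' @name pipeline
NULL

#' Locate a cryptogene for one mRNA and reconstruct its editing
#'
#' Runs [tdepleted_search()] of the mRNA against contigs, merges co-located
#' hits on the best contig/strand into an envelope region, pads it, extracts
#' the (strand-corrected) gene region and aligns it to the mRNA with
#' [align_editing()].
#'
#' @param mrna length-1 named character vector (mature transcript)
#' @param contigs named character vector (candidate maxicircle contigs)
#' @param search a [search_params()] for the depleted-space scan
#' @param align a [edit_align_params()]
#' @param pad padding (nt) added on both sides of the merged hit envelope
#' @return list: `alignment` (an `editing_alignment`), `region` (data.frame
#'   contig_id, start, end, strand of the extracted region), `hits` (the raw
#'   search hits); or NULL when no hit is found
#' @export
reconstruct_editing <- function(mrna, contigs,
                                search = search_params(seed_len = 10L,
                                                       min_hit_len = 30L,
                                                       min_identity = 0.8),
                                align = edit_align_params(), pad = 30L) {
  hits <- tdepleted_search(mrna, contigs, search)
  if (nrow(hits) == 0) return(NULL)
  top <- hits[1L, ]
  same <- hits[hits$subject_id == top$subject_id & hits$strand == top$strand, ,
               drop = FALSE]
  # envelope of hits near the top hit (within one gene length)
  near <- same[same$s_start < top$s_end + 2000L &
                 same$s_end > top$s_start - 2000L, , drop = FALSE]
  contig <- contigs[[top$subject_id]]
  L <- nchar(contig)
  start <- max(0L, min(near$s_start) - pad)
  end <- min(L, max(near$s_end) + pad)
  region_fwd <- substr(contig, start + 1L, end)
  region <- if (top$strand == "+") region_fwd else revcomp(region_fwd)
  names(region) <- top$subject_id
  aln <- align_editing(region, mrna, align)
  list(alignment = aln,
       region = data.frame(contig_id = top$subject_id, start = start,
                           end = end, strand = top$strand,
                           stringsAsFactors = FALSE),
       hits = hits)
}

.known_config_keys <- c("inputs", "outdir", "seed", "params", "verbose")
.known_input_keys <- c("mt_contigs", "mt_mrnas", "mt_rrnas", "nuclear_contigs",
                       "transcripts", "prey", "sl_refs", "sl_prey_refs")

#' Validate a pipeline configuration
#'
#' @param config named list, or path to a YAML file with the same structure:
#'   `inputs` (paths: mt_contigs, mt_mrnas, optional mt_rrnas,
#'   nuclear_contigs, transcripts, prey, sl_refs, optional sl_prey_refs),
#'   `outdir`, `seed`, optional `params` (per-module parameter blocks:
#'   search, align, grna, sl, decontam, mt_class, map_min_identity) and
#'   `verbose`. Unknown keys are rejected; referenced files must exist.
#' @return the validated config list (defaults filled in)
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$inputs) || is.null(config$outdir)) {
    stop("config requires 'inputs' and 'outdir'")
  }
  unknown <- setdiff(names(config$inputs), .known_input_keys)
  if (length(unknown)) stop("unknown input key(s): ", paste(unknown, collapse = ", "))
  required <- c("mt_contigs", "mt_mrnas", "nuclear_contigs", "transcripts",
                "prey", "sl_refs")
  missing <- setdiff(required, names(config$inputs))
  if (length(missing)) stop("missing input(s): ", paste(missing, collapse = ", "))
  for (k in names(config$inputs)) {
    if (!file.exists(config$inputs[[k]])) {
      stop("input file does not exist: ", k, " = ", config$inputs[[k]])
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$verbose)) config$verbose <- TRUE
  if (is.null(config$params)) config$params <- list()
  config
}

.stage <- function(name, verbose, expr) {
  if (verbose) log_msg("stage ", name, ": start")
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (verbose) log_msg("stage ", name, ": done")
  res
}

# flatten a nested list to key=value rows
.flatten_params <- function(x, prefix = "") {
  rows <- list()
  for (k in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    v <- x[[k]]
    if (is.list(v)) rows <- c(rows, .flatten_params(v, key))
    else rows[[length(rows) + 1L]] <- data.frame(
      key = key, value = paste(format(v, trim = TRUE), collapse = ","),
      stringsAsFactors = FALSE)
  }
  rows
}

#' Run the full pipeline
#'
#' @param config see [validate_config()]
#' @return invisibly, a list with the main result tables and `outdir`
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  verbose <- isTRUE(config$verbose)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(config$seed))
  pp <- config$params
  out <- function(f) file.path(config$outdir, f)

  inp <- .stage("load_inputs", verbose, {
    x <- lapply(config$inputs, read_fasta)
    names(x) <- names(config$inputs)
    x
  })

  # 1. decontamination
  dp <- do.call(decontam_params, pp$decontam %||% list())
  decontam <- .stage("decontam", verbose, {
    flags <- flag_prey_contigs(inp$nuclear_contigs, inp$prey, dp)
    write_table(flags, out("decontam.tsv"))
    flags
  })
  clean_contigs <- inp$nuclear_contigs[!decontam$flagged[
    match(names(inp$nuclear_contigs), decontam$contig_id)]]

  # 2. mitochondrial contig classification
  mtc <- do.call(mt_class_params, pp$mt_class %||% list())
  mt_classes <- .stage("mt_classify", verbose, {
    cls <- classify_contigs(inp$mt_contigs, inp$mt_mrnas, inp$mt_rrnas, mtc)
    write_table(cls$classes, out("mt_classes.tsv"))
    bb_rows <- do.call(rbind, cls$backbones[vapply(cls$backbones, nrow, 0L) > 0])
    write_table(if (is.null(bb_rows)) list() else bb_rows,
                out("mt_backbones.tsv"),
                schema = c("seq_id", "start", "end", "strand"))
    cls
  })
  maxis <- inp$mt_contigs[mt_classes$classes$contig_id[
    mt_classes$classes$label == "MAXICIRCLE_LIKE"]]
  minis <- inp$mt_contigs[mt_classes$classes$contig_id[
    mt_classes$classes$label == "MINICIRCLE_LIKE"]]

  # 3-5. cryptogene location, editing reconstruction, statistics
  ap <- do.call(edit_align_params, pp$align %||% list())
  transcripts_mt <- c(inp$mt_mrnas, inp$mt_rrnas)
  classes_mt <- c(rep("mRNA", length(inp$mt_mrnas)),
                  rep("rRNA", length(inp$mt_rrnas)))
  editing <- .stage("editing", verbose, {
    regions <- list(); events <- list(); stats <- list(); clusters <- list()
    alignments <- list()
    for (i in seq_along(transcripts_mt)) {
      tid <- names(transcripts_mt)[[i]]
      rec <- reconstruct_editing(transcripts_mt[i], maxis, align = ap)
      if (is.null(rec) || isTRUE(rec$alignment$unalignable)) {
        log_msg("editing: no cryptogene region recovered for ", tid)
        next
      }
      regions[[tid]] <- cbind(mrna_id = tid, rec$region,
                              stringsAsFactors = FALSE)
      aln <- rec$alignment
      alignments[[tid]] <- aln
      if (nrow(aln$events)) {
        events[[tid]] <- cbind(gene_id = aln$gene_id, mrna_id = tid,
                               aln$events, stringsAsFactors = FALSE)
      }
      st <- summarize_editing(aln)
      st$class <- classes_mt[[i]]
      stats[[tid]] <- st
      cl <- detect_deaminative_clusters(aln$events, seq_id = tid)
      if (nrow(cl)) clusters[[tid]] <- cl
    }
    stats <- do.call(rbind, stats)
    write_table(do.call(rbind, regions), out("cryptogene_regions.tsv"))
    write_table(do.call(rbind, events) %||% list(), out("edit_events.tsv"),
                schema = c("gene_id", "mrna_id", "kind", "gene_pos",
                           "mrna_pos", "run_len"))
    write_table(stats, out("editing_stats.tsv"))
    write_table(do.call(rbind, clusters) %||% list(), out("deam_clusters.tsv"),
                schema = c("seq_id", "start", "end", "n_edits", "n_c_to_u",
                           "n_a_to_i"))
    summary <- aggregate_editing(stats[stats$class == "mRNA", , drop = FALSE])
    write_table(summary, out("editing_summary.tsv"))
    list(stats = stats, summary = summary, alignments = alignments,
         clusters = do.call(rbind, clusters))
  })

  # 6. gRNA detection on minicircle-like contigs
  gp <- do.call(grna_params, pp$grna %||% list())
  grna <- .stage("grna", verbose, {
    hits <- do.call(rbind, lapply(names(minis), function(cid) {
      find_grnas(minis[cid], inp$mt_mrnas, gp)
    }))
    write_table(hits %||% list(), out("grna_hits.tsv"),
                schema = names(.empty_grna_hits()))
    hits %||% .empty_grna_hits()
  })

  # 7. SL detection
  refs <- sl_refs(
    name = c(names(inp$sl_refs), names(inp$sl_prey_refs)),
    seq = c(unname(inp$sl_refs), unname(inp$sl_prey_refs)),
    source = c(rep("TARGET", length(inp$sl_refs)),
               rep("PREY", length(inp$sl_prey_refs))))
  slp <- pp$sl %||% list()
  sl <- .stage("sl", verbose, {
    res <- do.call(sl_fraction, c(list(inp$transcripts, refs), slp))
    write_table(res$calls, out("sl_calls.tsv"))
    write_table(res$summary, out("sl_summary.tsv"))
    res
  })

  # 8. transcript mapping and polarity (SL trimmed before mapping)
  mapping <- .stage("map_polarity", verbose, {
    tx <- inp$transcripts
    if (nrow(sl$calls)) {
      for (r in seq_len(nrow(sl$calls))) {
        id <- sl$calls$transcript_id[r]
        cut <- sl$calls$offset[r] + sl$calls$matched_len[r]
        tx[id] <- substr(tx[[id]], cut + 1L, nchar(tx[[id]]))
      }
    }
    if (length(clean_contigs)) {
      mm <- map_transcripts(tx, clean_contigs,
                            min_identity = pp$map_min_identity %||% 0.90)
    } else {
      log_msg("map_polarity: no contigs left after decontamination")
      mm <- list(mappings = data.frame(
        transcript_id = character(0), contig_id = character(0),
        t_start = integer(0), t_end = integer(0), c_start = integer(0),
        c_end = integer(0), strand = character(0), identity = numeric(0),
        coverage = numeric(0), stringsAsFactors = FALSE),
        summary = data.frame(n_transcripts = length(tx), n_mapped = 0L,
                             fraction_mapped = 0))
    }
    write_table(mm$mappings, out("transcript_mappings.tsv"))
    write_table(mm$summary, out("mapping_summary.tsv"))
    write_bed(mm$mappings, out("gene_mappings.bed"))
    if (nrow(mm$mappings)) {
      pol <- polarity_report(mm$mappings)
    } else {
      pol <- list(contigs = list(), intergenic = list())
    }
    write_table(pol$contigs, out("polarity.tsv"),
                schema = c("contig_id", "n_genes", "same_strand_fraction",
                           "strand_runs", "n_intergenic", "mean_intergenic",
                           "n_overlapping_flagged"))
    write_table(pol$intergenic, out("intergenic.tsv"),
                schema = c("contig_id", "left_gene", "right_gene", "distance",
                           "overlapping"))
    c(mm, pol)
  })

  # manifest: parameters + input checksums (no timestamps: byte-stable reruns)
  .stage("manifest", verbose, {
    sums <- vapply(config$inputs, function(p) unname(tools::md5sum(p)), "")
    rows <- c(
      list(data.frame(key = "package_version",
                      value = as.character(utils::packageVersion("kinetoedit")),
                      stringsAsFactors = FALSE),
           data.frame(key = "seed", value = as.character(config$seed),
                      stringsAsFactors = FALSE)),
      lapply(names(sums), function(k) data.frame(
        key = paste0("md5.", k), value = sums[[k]], stringsAsFactors = FALSE)),
      .flatten_params(list(decontam = unclass(dp), align = unclass(ap),
                           grna = unclass(gp),
                           mt_class = unclass(mtc), sl = slp,
                           map_min_identity = pp$map_min_identity %||% 0.90)))
    write_table(do.call(rbind, rows), out("manifest.tsv"))
  })

  invisible(list(outdir = config$outdir, decontam = decontam,
                 mt_classes = mt_classes$classes, editing = editing,
                 grna = grna, sl = sl, mapping = mapping))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
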
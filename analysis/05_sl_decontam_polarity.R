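#!/usr/bin/env Rscript
# Nuclear-genome analyses on the simulated data: spliced-leader fractions
# against truth, prey decontamination confusion counts, gene polarity and
# intergenic spacing, and a stem-loop motif scan of the simulated 12S-like
# rRNA gene. Writes results/nuclear_summary.tsv.

library(kinetoedit)

sim_dir <- file.path("results", "simdata", "ankaliazontas")
pipe_dir <- file.path("results", "pipeline", "ankaliazontas")
if (!dir.exists(pipe_dir)) stop("run analysis/02_run_pipeline.R first")

## spliced leaders
sl_truth <- readLines(file.path(sim_dir, "truth", "sl_ids.txt"))
calls <- read_table(file.path(pipe_dir, "sl_calls.tsv"))
target_ids <- calls$transcript_id[calls$source == "TARGET"]
n_tx <- read_table(file.path(pipe_dir, "mapping_summary.tsv"))$n_transcripts[1]
cat(sprintf("SL-positive transcripts: detected %d, truth %d (%.0f%% of %d transcripts)\n",
            length(target_ids), length(sl_truth),
            100 * length(sl_truth) / n_tx, n_tx))
cat(sprintf("  agreement with truth: %d/%d\n",
            length(intersect(target_ids, sl_truth)), length(sl_truth)))

## decontamination
cont_truth <- readLines(file.path(sim_dir, "truth", "contaminated_ids.txt"))
dec <- read_table(file.path(pipe_dir, "decontam.tsv"))
tp <- sum(dec$contig_id[dec$flagged] %in% cont_truth)
fp <- sum(!dec$contig_id[dec$flagged] %in% cont_truth)
cat(sprintf("decontamination: %d/%d contaminated contigs flagged, %d false positives\n",
            tp, length(cont_truth), fp))

## polarity and spacing
pol <- read_table(file.path(pipe_dir, "polarity.tsv"))
cat(sprintf("gene clusters: %d contigs, same-strand fraction %s, mean intergenic %s bp\n",
            nrow(pol), paste(round(pol$same_strand_fraction, 2), collapse = "/"),
            paste(round(pol$mean_intergenic), collapse = "/")))

## stem-loop motif scan of the simulated rRNA gene
hp <- read_table(file.path(sim_dir, "truth", "mt_gene_intervals.tsv"))
rrna <- read_fasta(file.path(sim_dir, "mt_rrnas.fasta"))
pat <- motif_pattern(motif_stem_open("s", 6), motif_literal("GAAA"),
                     motif_stem_close("s", 0))
mh <- scan_motif(rrna[1], pat)
cat(sprintf("stem-loop motif scan of %s: %d hit(s)", names(rrna)[1], nrow(mh$hits)))
if (nrow(mh$hits)) cat(sprintf(" at [%d,%d)", mh$hits$start[1], mh$hits$end[1]))
cat("\n")

summary <- data.frame(
  metric = c("sl_detected", "sl_truth", "contaminated_flagged",
             "contaminated_truth", "false_positive_flags",
             "mean_intergenic_bp", "motif_hits"),
  value = c(length(target_ids), length(sl_truth), tp, length(cont_truth), fp,
            pol$mean_intergenic[1], nrow(mh$hits)))
write_table(summary, file.path("results", "nuclear_summary.tsv"))
cat("table written to results/nuclear_summary.tsv\n")
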
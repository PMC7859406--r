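#!/usr/bin/env Rscript
# Compare the pipeline's reconstructed editing statistics against the
# generator's ground truth, per gene: U-insertion/deletion counts, percent
# expansion, pattern class and the deaminative cluster. Writes
# results/editing_recovery.tsv and prints what it found.

library(kinetoedit)

sim_dir <- file.path("results", "simdata", "ankaliazontas")
pipe_dir <- file.path("results", "pipeline", "ankaliazontas")
if (!dir.exists(pipe_dir)) stop("run analysis/02_run_pipeline.R first")

truth <- read_table(file.path(sim_dir, "truth", "mt_genes.tsv"))
stats <- read_table(file.path(pipe_dir, "editing_stats.tsv"))

cmp <- merge(truth, stats, by.x = "gene_id", by.y = "mrna_id",
             suffixes = c("_truth", "_rec"))
cmp$ins_exact <- cmp$n_ins_truth == cmp$n_ins_rec
cmp$del_exact <- cmp$n_del_truth == cmp$n_del_rec
out <- cmp[, c("gene_id", "class_truth", "gene_len_truth", "n_ins_truth",
               "n_ins_rec", "n_del_truth", "n_del_rec", "pct_expansion_rec",
               "pattern_truth", "pattern_rec", "ins_exact", "del_exact")]
names(out)[names(out) == "class_truth"] <- "class"
write_table(out, file.path("results", "editing_recovery.tsv"))

mrna <- out[out$class == "mRNA", ]
cat(sprintf("per-gene U-indel counts recovered exactly: %d/%d genes\n",
            sum(mrna$ins_exact & mrna$del_exact), nrow(mrna)))
cat(sprintf("recovered means: %.1f insertions, %.1f deletions (truth %.1f / %.1f)\n",
            mean(mrna$n_ins_rec), mean(mrna$n_del_rec),
            mean(mrna$n_ins_truth), mean(mrna$n_del_truth)))
cat(sprintf("mean transcript expansion: %.1f%% (range %.1f-%.1f%%)\n",
            mean(mrna$pct_expansion_rec), min(mrna$pct_expansion_rec),
            max(mrna$pct_expansion_rec)))
cat(sprintf("pattern classes recovered: %d/%d\n",
            sum(out$pattern_truth == out$pattern_rec), nrow(out)))

cl <- read_table(file.path(pipe_dir, "deam_clusters.tsv"))
if (nrow(cl)) {
  cat(sprintf("deaminative cluster: %d edits (%d C-to-U + %d A-to-I) over %d nt on %s\n",
              cl$n_edits[1], cl$n_c_to_u[1], cl$n_a_to_i[1],
              cl$end[1] - cl$start[1], cl$seq_id[1]))
} else {
  cat("no deaminative clusters reported\n")
}
cat("table written to results/editing_recovery.tsv\n")
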
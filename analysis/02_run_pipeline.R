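#!/usr/bin/env Rscript
# Run the full analysis pipeline (decontaminate -> classify mt contigs ->
# locate cryptogenes -> reconstruct editing -> statistics -> gRNA -> SL ->
# mapping/polarity) on the ankaliazontas-like dataset from 01_simulate_data.R.
# All stage TSVs land in results/pipeline/ankaliazontas/.

library(kinetoedit)

dir <- file.path("results", "simdata", "ankaliazontas")
if (!dir.exists(dir)) stop("run analysis/01_simulate_data.R first")

config <- list(
  inputs = list(
    mt_contigs = file.path(dir, "mt_contigs.fasta"),
    mt_mrnas = file.path(dir, "mt_mrnas.fasta"),
    mt_rrnas = file.path(dir, "mt_rrnas.fasta"),
    nuclear_contigs = file.path(dir, "nuclear_contigs.fasta"),
    transcripts = file.path(dir, "transcripts.fasta"),
    prey = file.path(dir, "prey.fasta"),
    sl_refs = file.path(dir, "sl_refs.fasta")),
  outdir = file.path("results", "pipeline", "ankaliazontas"),
  seed = 42L)

res <- run_pipeline(config)

cat("\n== species-level editing summary (mt mRNAs) ==\n")
print(res$editing$summary)
cat("\n== SL summary ==\n")
print(res$sl$summary)
cat("\n== transcript mapping ==\n")
print(res$mapping$summary)
cat("\nstage outputs in", config$outdir, "\n")
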
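#!/usr/bin/env Rscript
# Generate the two study-like synthetic datasets with ground truth.
#
# "ankaliazontas-like": pan-editing dominant, U insertions ~389 per transcript
# (range 166-885), deletions ~29 (13-49), one deaminative cluster (8 C-to-U +
# 4 A-to-I over 30 nt) in an rRNA-like gene, circular-mapping maxicircles and
# 1300-2200 bp minicircles with two ~85 bp gRNA cassettes each.
# "spiralis-like": terminal editing dominant, insertions ~166 (19-331),
# deletions ~43 (17-80), linear ~600 bp minicircles with one cassette.
#
# Writes FASTA + truth TSVs under results/simdata/<preset>/.

library(kinetoedit)

seed <- 42L
for (preset in c("ankaliazontas", "spiralis")) {
  params <- sim_params(preset, seed = seed)
  bundle <- simulate_bundle(params)
  dir <- file.path("results", "simdata", preset)
  write_bundle(bundle, dir)
  tg <- bundle$mt$truth$genes
  tg <- tg[tg$class == "mRNA", ]
  cat(sprintf(
    "[%s] %d mt genes: mean %d U ins (range %d-%d), mean %d U del, mean expansion %.1f%%\n",
    preset, nrow(tg), round(mean(tg$n_ins)), min(tg$n_ins), max(tg$n_ins),
    round(mean(tg$n_del)), mean(tg$pct_expansion)))
  cat(sprintf(
    "[%s] %d minicircles (%d cassettes), %d nuclear genes, %d/%d SL-bearing transcripts, %d contaminated contig(s)\n",
    preset, length(bundle$mt$minicircles), nrow(bundle$mt$truth$cassettes),
    nrow(bundle$nuclear$truth$genes), length(bundle$nuclear$truth$sl_ids),
    length(bundle$transcripts), length(bundle$contam$truth$contaminated_ids)))
  cat("  written to", dir, "\n")
}
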
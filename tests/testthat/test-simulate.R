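test_that("truth events reproduce every mature mRNA exactly", {
  mt <- simulate_mt(sim_params(seed = 42))
  mats <- c(mt$mrnas, mt$rrnas)
  for (g in mt$truth$genes$gene_id) {
    ev <- mt$truth$events[mt$truth$events$gene_id == g, , drop = FALSE]
    rec <- apply_edit_events(mt$gene_seqs[[g]], ev)
    expect_identical(rec, mats[[g]])
  }
  # cassettes are wobble-perturbed reverse complements of their mRNA blocks
  tr <- mt$truth$cassettes
  for (i in seq_len(nrow(tr))) {
    cas <- substr(mt$minicircles[[tr$minicircle_id[i]]],
                  tr$cassette_start[i] + 1L, tr$cassette_end[i])
    if (tr$strand[i] == "-") cas <- revcomp(cas)
    block <- substr(mt$mrnas[[tr$mrna_id[i]]], tr$mrna_start[i] + 1L,
                    tr$mrna_end[i])
    gch <- strsplit(cas, "", fixed = TRUE)[[1L]]
    tch <- strsplit(revcomp(block), "", fixed = TRUE)[[1L]]
    wob <- sum((gch == "G" & tch == "A") | (gch == "T" & tch == "C"))
    expect_identical(wob, tr$n_wobble[i])
    expect_identical(sum(gch == tch), nchar(cas) - wob)
  }
})

test_that("identical parameters give byte-identical bundles", {
  p <- sim_params(seed = 123, n_genes = 3L, n_minicircles = 3L,
                  n_nuclear_genes = 6L)
  b1 <- simulate_bundle(p)
  b2 <- simulate_bundle(p)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  b3 <- simulate_bundle(sim_params(seed = 124, n_genes = 3L,
                                   n_minicircles = 3L, n_nuclear_genes = 6L))
  expect_false(identical(b1$mrnas, b3$mrnas))
})

test_that("realized insertion means converge to the configured mean", {
  mt <- simulate_mt(sim_params(seed = 99, n_genes = 500L))
  tg <- mt$truth$genes[mt$truth$genes$class == "mRNA", ]
  expect_lt(abs(mean(tg$n_ins) - 389) / 389, 0.05)
  expect_true(all(tg$n_ins >= 1))
  expect_true(all(tg$n_ins <= 885))
})

test_that("the deaminative cluster is planted exactly as configured", {
  mt <- simulate_mt(sim_params(seed = 42))
  ev <- mt$truth$events[mt$truth$events$gene_id == "rRNA12S", ]
  expect_identical(sum(ev$kind == "C_TO_U"), 8L)
  expect_identical(sum(ev$kind == "A_TO_I"), 4L)
  expect_lte(max(ev$gene_pos) - min(ev$gene_pos) + 1L, 30L)
  # no U indels on the rRNA-like gene
  expect_false(any(ev$kind %in% c("U_INS", "U_DEL")))
})

test_that("nuclear clusters carry same-strand genes at the configured spacing", {
  p <- sim_params(seed = 3, n_nuclear_genes = 15L, genes_per_contig = 15L,
                  intergenic_mode = "fixed", sl_fraction = 0)
  nuc <- simulate_nuclear(p)
  tr <- nuc$truth$genes
  expect_identical(nrow(tr), 15L)
  expect_identical(length(unique(tr$strand)), 1L)
  gaps <- tr$start[-1] - tr$end[-15]
  expect_true(all(gaps == 76L))
  # polarity on truth mappings
  pol <- polarity_report(data.frame(transcript_id = tr$gene_id,
                                    contig_id = tr$contig_id,
                                    c_start = tr$start, c_end = tr$end,
                                    strand = tr$strand))
  expect_identical(pol$contigs$same_strand_fraction, 1)
  expect_identical(pol$contigs$mean_intergenic, 76)
})

test_that("SL-bearing fractions follow the configured Bernoulli rate", {
  p <- sim_params(seed = 7, n_nuclear_genes = 1000L, sl_fraction = 0.70)
  nuc <- simulate_nuclear(p)
  n_sl <- length(nuc$truth$sl_ids)
  ci <- qnorm(0.995) * sqrt(0.7 * 0.3 * 1000)
  expect_lt(abs(n_sl - 700), ci)
  expect_true(all(startsWith(nuc$transcripts[nuc$truth$sl_ids], p$sl_seq)))

  p0 <- sim_params(seed = 7, n_nuclear_genes = 50L, sl_fraction = 0)
  expect_identical(length(simulate_nuclear(p0)$truth$sl_ids), 0L)
})

test_that("contamination is embedded at the configured identity and length", {
  # 95% / 120 bp: all contaminated contigs flagged at the standard thresholds
  p <- sim_params(seed = 13, n_nuclear_genes = 12L, genes_per_contig = 4L,
                  n_contaminated = 2L)
  nuc <- simulate_nuclear(p)
  ct <- simulate_contamination(p, nuc$contigs)
  fl <- flag_prey_contigs(ct$contigs, ct$prey)
  expect_setequal(fl$contig_id[fl$flagged], ct$truth$contaminated_ids)

  # 90% identity: below the 93% rule, nothing flagged
  p90 <- sim_params(seed = 13, n_nuclear_genes = 12L, genes_per_contig = 4L,
                    n_contaminated = 2L,
                    prey = c(n_contigs = 4, identity = 0.90, seg_len = 120))
  ct90 <- simulate_contamination(p90, nuc$contigs)
  expect_false(any(flag_prey_contigs(ct90$contigs, ct90$prey)$flagged))

  # 99% identity but only 80 bp: below the length rule
  p80 <- sim_params(seed = 13, n_nuclear_genes = 12L, genes_per_contig = 4L,
                    n_contaminated = 2L,
                    prey = c(n_contigs = 4, identity = 0.99, seg_len = 80))
  ct80 <- simulate_contamination(p80, nuc$contigs)
  expect_false(any(flag_prey_contigs(ct80$contigs, ct80$prey)$flagged))
})

test_that("infeasible deletion parameters fail loudly, naming the gene", {
  p <- sim_params(seed = 1, n_genes = 1L, gc = 1)  # no A/T drawn at all
  expect_error(simulate_mt(p), "infeasible.*mtgene01")
})
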
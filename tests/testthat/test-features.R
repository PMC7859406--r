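test_that("decontamination thresholds are exact and inclusive", {
  set.seed(40)
  prey_seg <- random_dna(100)

  # exactly 93% identity over exactly 100 bp: flagged
  c93 <- embed_segment(mutate_at(prey_seg, round(seq(8, 92, length.out = 7))))
  f93 <- flag_prey_contigs(c93, c(p = prey_seg))
  expect_true(f93$flagged)
  expect_identical(f93$best_identity, 0.93)
  expect_identical(f93$best_len, 100L)

  # 92% over 100 bp: below the identity rule
  c92 <- embed_segment(mutate_at(prey_seg, round(seq(8, 92, length.out = 8))))
  expect_false(flag_prey_contigs(c92, c(p = prey_seg))$flagged)

  # 92.9% over 1000 bp: the best local alignment is the full segment
  seg1k <- random_dna(1000)
  c929 <- embed_segment(mutate_at(seg1k, round(seq(8, 993, length.out = 71))))
  f929 <- flag_prey_contigs(c929, c(p = seg1k))
  expect_false(f929$flagged)
  expect_identical(f929$best_identity, 0.929)

  # 100% over 99 bp: below the length rule
  prey99 <- substr(prey_seg, 1, 99)
  f99 <- flag_prey_contigs(embed_segment(prey99), c(p = prey99))
  expect_false(f99$flagged)
  expect_identical(f99$best_len, 99L)

  # 95% over 120 bp: comfortably flagged
  seg120 <- random_dna(120)
  c95 <- embed_segment(mutate_at(seg120, round(seq(10, 110, length.out = 6))))
  expect_true(flag_prey_contigs(c95, c(p = seg120))$flagged)

  expect_error(flag_prey_contigs(c95, character(0)), "non-empty")
})

test_that("transcripts map unspliced at the configured identity floor", {
  set.seed(41)
  contig <- c(ctg = random_dna(3000))
  tx_exact <- c(t1 = substr(contig[[1]], 1001, 1400))
  mm <- map_transcripts(tx_exact, contig)
  expect_identical(mm$mappings$identity, 1)
  expect_identical(mm$mappings$coverage, 1)
  expect_identical(c(mm$mappings$c_start, mm$mappings$c_end), c(1000L, 1400L))

  # 85% identity transcript is rejected at the 90% floor
  tx_low <- c(t2 = mutate_at(tx_exact[[1]], round(seq(5, 395, length.out = 60))))
  mm2 <- map_transcripts(tx_low, contig, min_identity = 0.90,
                         search = search_params(seed_len = 8L))
  expect_identical(nrow(mm2$mappings), 0L)
  expect_identical(mm2$summary$fraction_mapped, 0)

  # mapped fraction by construction: 7 of 10 transcripts have a locus
  placed <- setNames(lapply(seq(0, 1800, by = 300), function(o) {
    substr(contig[[1]], o + 1, o + 250)
  }), paste0("p", 1:7))
  orphans <- setNames(lapply(1:3, function(i) random_dna(250)), paste0("o", 1:3))
  mm3 <- map_transcripts(c(unlist(placed), unlist(orphans)), contig)
  expect_identical(mm3$summary$fraction_mapped, 0.7)
})

test_that("polarity reports strand runs and intergenic distances", {
  # the 15-gene same-strand contig spaced exactly 76 nt
  g <- data.frame(transcript_id = sprintf("g%02d", 1:15), contig_id = "ctg",
                  c_start = cumsum(c(200, rep(500 + 76, 14))),
                  stringsAsFactors = FALSE)
  g$c_end <- g$c_start + 500L
  g$strand <- "+"
  pol <- polarity_report(g)
  expect_identical(pol$contigs$n_genes, 15L)
  expect_identical(pol$contigs$same_strand_fraction, 1)
  expect_identical(pol$contigs$mean_intergenic, 76)
  expect_identical(pol$contigs$strand_runs, "15")
  expect_identical(nrow(pol$intergenic), 14L)

  # alternating strands
  alt <- data.frame(transcript_id = paste0("a", 1:4), contig_id = "c2",
                    c_start = c(0L, 200L, 400L, 600L),
                    c_end = c(100L, 300L, 500L, 700L),
                    strand = c("+", "-", "+", "-"), stringsAsFactors = FALSE)
  pa <- polarity_report(alt)
  expect_identical(pa$contigs$same_strand_fraction, 0.5)
  expect_identical(pa$contigs$strand_runs, "1,1,1,1")
  # sum of strand runs equals the number of genes
  expect_identical(sum(as.integer(strsplit(pa$contigs$strand_runs, ",")[[1]])),
                   pa$contigs$n_genes)

  # single gene: no intergenic entries
  ps <- polarity_report(alt[1, ])
  expect_identical(ps$contigs$n_intergenic, 0L)
  expect_identical(ps$contigs$same_strand_fraction, 1)

  # overlapping mappings are clipped to 0 and flagged
  ov <- data.frame(transcript_id = c("x1", "x2"), contig_id = "c3",
                   c_start = c(0L, 80L), c_end = c(100L, 200L),
                   strand = "+", stringsAsFactors = FALSE)
  po <- polarity_report(ov)
  expect_identical(po$contigs$mean_intergenic, 0)
  expect_identical(po$contigs$n_overlapping_flagged, 1L)
  expect_error(polarity_report(ov[0, ]), "no mappings")
})
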
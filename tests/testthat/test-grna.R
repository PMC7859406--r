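test_that("a wobble-perturbed antisense cassette is found with exact pair tallies", {
  set.seed(20)
  mrna <- random_dna(500)
  block <- substr(mrna, 201, 240)            # 40-nt block
  gr <- strsplit(revcomp(block), "", fixed = TRUE)[[1L]]
  blc <- strsplit(block, "", fixed = TRUE)[[1L]]
  # two wobble conversions: mRNA U paired by gRNA G instead of A
  tpos <- which(blc == "T")[1:2]
  for (i in tpos) gr[40 - i + 1L] <- "G"
  cassette <- paste0(gr, collapse = "")

  backbone <- random_dna(600)
  mini <- paste0(substr(backbone, 1, 450), cassette, substr(backbone, 451, 600))
  h <- find_grnas(c(m1 = mini), c(mr = mrna))
  expect_identical(nrow(h), 1L)
  expect_identical(h$mrna_id, "mr")
  # the duplex covers the 40-nt cassette; flank columns that happen to pair by
  # chance may extend it by a base or two
  dup_len <- h$cassette_end - h$cassette_start
  expect_lte(abs(h$cassette_start - 450L), 2L)
  expect_lte(abs(h$cassette_end - 490L), 2L)
  expect_lte(abs(h$mrna_start - 200L), 2L)
  expect_lte(abs(h$mrna_end - 240L), 2L)
  expect_identical(h$n_wobble, 2L)
  expect_identical(h$n_mismatch, 0L)
  expect_identical(h$n_wc, dup_len - 2L)

  # tallies are reproducible by independently re-walking the two substrings
  g_seq <- if (h$strand == "+") substr(mini, h$cassette_start + 1, h$cassette_end) else
    revcomp(substr(mini, h$cassette_start + 1, h$cassette_end))
  t_seq <- revcomp(substr(mrna, h$mrna_start + 1, h$mrna_end))
  gch <- strsplit(g_seq, "", fixed = TRUE)[[1L]]
  tch <- strsplit(t_seq, "", fixed = TRUE)[[1L]]
  wc <- sum(gch == tch)
  wob <- sum((gch == "G" & tch == "A") | (gch == "T" & tch == "C"))
  expect_identical(c(wc, wob, dup_len - wc - wob),
                   c(h$n_wc, h$n_wobble, h$n_mismatch))

  # shuffled minicircle: no hits at defaults
  sh <- paste0(sample(strsplit(mini, "")[[1L]]), collapse = "")
  expect_identical(nrow(find_grnas(c(s = sh), c(mr = mrna))), 0L)
})

test_that("wobble support can be switched off", {
  set.seed(21)
  mrna <- random_dna(300)
  block <- substr(mrna, 101, 140)
  gr <- strsplit(revcomp(block), "", fixed = TRUE)[[1L]]
  blc <- strsplit(block, "", fixed = TRUE)[[1L]]
  tpos <- which(blc == "T")[1:6]
  for (i in tpos) gr[40 - i + 1L] <- "G"
  mini <- c(m = paste0(random_dna(100), paste0(gr, collapse = ""), random_dna(100)))
  h_on <- find_grnas(mini, c(mr = mrna))
  expect_identical(h_on$n_wobble, 6L)
  # without wobble the 6 conversions count as mismatches: 6/40 > 10% cap
  h_off <- find_grnas(mini, c(mr = mrna), grna_params(allow_wobble = FALSE))
  expect_identical(nrow(h_off), 0L)
})

test_that("shared backbones are segmented at the configured identity", {
  set.seed(22)
  bb <- random_dna(400)
  contigs <- setNames(vapply(1:10, function(i) {
    paste0(random_dna(80), bb, random_dna(80))
  }, ""), paste0("c", 1:10))
  res <- find_backbone(contigs)
  for (cid in names(contigs)) {
    expect_identical(nrow(res[[cid]]), 1L)
    expect_lte(abs((res[[cid]]$end - res[[cid]]$start) - 400L), 10L)
  }

  # no shared region
  lone <- setNames(vapply(1:4, function(i) random_dna(500), ""), paste0("r", 1:4))
  res2 <- find_backbone(lone)
  expect_true(all(vapply(res2, nrow, 0L) == 0L))

  # backbone at 92% identity: detected at 0.90, not at 0.95
  bb2 <- random_dna(400)
  conts <- setNames(vapply(1:4, function(i) {
    paste0(random_dna(60), mutate_at(bb2, round(seq(9, 391, length.out = 32))),
           random_dna(60))
  }, ""), paste0("m", 1:4))
  conts[["ref"]] <- paste0(random_dna(60), bb2, random_dna(60))
  # short seeds: at 92% identity few long exact words survive
  sp <- function(mi) search_params(seed_len = 8L, min_identity = mi,
                                   min_hit_len = 100L, max_hits = 1000L)
  r90 <- find_backbone(conts, min_identity = 0.90, search = sp(0.90))
  expect_gt(nrow(r90[["ref"]]), 0L)
  r95 <- find_backbone(conts, min_identity = 0.95, search = sp(0.95))
  expect_identical(nrow(r95[["ref"]]), 0L)
})

test_that("circular-mapping contigs are detected via duplicated termini", {
  set.seed(23)
  circle <- random_dna(900)
  lin <- paste0(circle, substr(circle, 1, 120))
  r <- detect_circularity(c(x = lin))
  expect_true(r$circular)
  expect_identical(r$overlap_len, 120L)

  # rotation invariance of the underlying circle
  for (rot in c(100, 447, 800)) {
    rotated <- paste0(substr(circle, rot + 1, 900), substr(circle, 1, rot))
    lr <- paste0(rotated, substr(rotated, 1, 120))
    expect_true(detect_circularity(c(x = lr))$circular)
  }

  expect_false(detect_circularity(c(x = random_dna(900)))$circular)

  # one substitution in the duplicated terminus, tolerated at max_mismatch 1
  lin1 <- paste0(circle, mutate_at(substr(circle, 1, 120), 60))
  r1 <- detect_circularity(c(x = lin1), max_mismatch = 1L)
  expect_true(r1$circular)
  expect_identical(r1$overlap_len, 120L)
  expect_error(detect_circularity(c(x = "ACGT"), min_overlap = 50L), "shorter")
})

test_that("contigs are classified into maxicircle- and minicircle-like", {
  set.seed(24)
  mt <- simulate_mt(sim_params(seed = 24, n_genes = 4L, n_minicircles = 5L,
                               genes_per_maxicircle = 2L))
  contigs <- c(mt$maxicircles, mt$minicircles,
               setNames(random_dna(1000), "rand1"))
  cls <- classify_contigs(contigs, mt$mrnas, mt$rrnas)$classes
  lab <- setNames(cls$label, cls$contig_id)
  expect_true(all(lab[names(mt$maxicircles)] == "MAXICIRCLE_LIKE"))
  expect_true(all(lab[names(mt$minicircles)] == "MINICIRCLE_LIKE"))
  expect_identical(unname(lab["rand1"]), "UNCLASSIFIED")
  expect_true(all(cls$circular[cls$contig_id %in% names(mt$maxicircles)]))
})
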
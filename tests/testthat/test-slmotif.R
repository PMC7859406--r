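SL <- "TTACAGTTTCTGTACTT"  # the prokinetoplastid SL 3' region

test_that("SL suffixes are detected near the transcript 5' end", {
  refs <- sl_refs(c("target", "prey"), c(SL, "GGACAGTTTCTGTAGAA"),
                  c("TARGET", "PREY"))
  set.seed(30)
  payload <- random_dna(200)

  call <- detect_sl(c(t1 = paste0(SL, payload)), refs)
  expect_identical(call$offset, 0L)
  expect_identical(call$matched_len, 17L)
  expect_identical(call$mismatches, 0L)
  expect_identical(call$source, "TARGET")

  # last 12 nt of the reference with one substitution
  suf <- mutate_at(substr(SL, 6, 17), 5)
  call2 <- detect_sl(c(t2 = paste0(suf, payload)), refs,
                     max_mismatch = 1L, min_suffix = 10L)
  expect_identical(call2$matched_len, 12L)
  expect_identical(call2$mismatches, 1L)

  expect_null(detect_sl(c(t3 = payload), refs))

  # a transcript carrying the prey SL is attributed to PREY
  prey_sl <- "GGACAGTTTCTGTAGAA"
  call3 <- detect_sl(c(t4 = paste0(prey_sl, payload)), refs)
  expect_identical(call3$source, "PREY")

  # identical target and prey references tie -> AMBIGUOUS
  refs2 <- sl_refs(c("a", "b"), c(SL, SL), c("TARGET", "PREY"))
  call4 <- detect_sl(c(t5 = paste0(SL, payload)), refs2)
  expect_identical(call4$source, "AMBIGUOUS")
})

test_that("SL fractions partition the transcript set", {
  set.seed(31)
  refs <- sl_refs("target", SL, "TARGET")
  tx <- setNames(vapply(1:100, function(i) random_dna(150), ""),
                 sprintf("t%03d", 1:100))
  with_sl <- sample(100, 70)
  tx[with_sl] <- paste0(SL, tx[with_sl])
  res <- sl_fraction(tx, refs, max_mismatch = 0L)
  expect_identical(res$summary$count[res$summary$source == "TARGET"], 70L)
  expect_identical(res$summary$fraction[res$summary$source == "TARGET"], 0.70)
  expect_identical(sum(res$summary$count), 100L)

  # trimming at offset + matched_len leaves no SL suffix behind
  for (r in seq_len(nrow(res$calls))) {
    id <- res$calls$transcript_id[r]
    rest <- substr(tx[[id]], res$calls$offset[r] + res$calls$matched_len[r] + 1L,
                   nchar(tx[[id]]))
    expect_null(detect_sl(setNames(rest, id), refs, max_mismatch = 0L))
  }

  res0 <- sl_fraction(setNames(vapply(1:20, function(i) random_dna(100), ""),
                               paste0("x", 1:20)), refs, max_mismatch = 0L)
  expect_identical(res0$summary$fraction[res0$summary$source == "TARGET"], 0)
})

test_that("stem-loop motifs match with pairing constraints on both strands", {
  pat <- motif_pattern(motif_stem_open("s1", 4), motif_literal("GAAA"),
                       motif_stem_close("s1", 0))
  h <- scan_motif(c(x = "GGCGGAAACGCC"), pat)
  expect_identical(nrow(h$hits), 1L)
  expect_identical(c(h$hits$start, h$hits$end), c(0L, 12L))

  expect_identical(nrow(scan_motif(c(x = "GGCGGAAAGGGG"), pat)$hits), 0L)

  h2 <- scan_motif(c(x = "ACGA"), motif_pattern(motif_literal("ACGT", 1)))
  expect_gte(nrow(h2$hits), 1L)

  # G:U wobble tolerated in stems when allowed
  patgu <- motif_pattern(motif_stem_open("s1", 4), motif_literal("GAAA"),
                         motif_stem_close("s1", 0, allow_gu = TRUE))
  patwc <- motif_pattern(motif_stem_open("s1", 4), motif_literal("GAAA"),
                         motif_stem_close("s1", 0, allow_gu = FALSE))
  s <- "GGTGGAAACGCC"  # T:G wobble in column 3
  expect_identical(nrow(scan_motif(c(x = s), patgu)$hits), 1L)
  expect_identical(nrow(scan_motif(c(x = s), patwc)$hits), 0L)

  expect_error(motif_pattern(motif_stem_close("nope")), "prior STEM_OPEN")
})

test_that("scan_motif agrees with a brute-force window matcher", {
  set.seed(32)
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  brute <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    out <- integer(0)
    for (i in seq_len(length(ch) - 11L)) {
      w <- ch[i:(i + 11L)]
      if (paste0(w[5:8], collapse = "") == "GAAA" &&
          all(pairs_ok(w[1:4], w[12:9]))) out <- c(out, i - 1L)
    }
    out
  }
  pat <- motif_pattern(motif_stem_open("s1", 4), motif_literal("GAAA"),
                       motif_stem_close("s1", 0))
  for (rep in 1:10) {
    s <- paste0(random_dna(80), "GGCGGAAACGCC", random_dna(80))
    got <- scan_motif(setNames(s, "x"), pat)
    plus <- got$hits[got$hits$strand == "+", , drop = FALSE]
    expect_identical(sort(plus$start), sort(brute(s)))
  }
})

test_that("identical vs compensatory stem columns are counted against a reference", {
  pat <- motif_pattern(motif_stem_open("s1", 4), motif_literal("GAAA"),
                       motif_stem_close("s1", 0))
  h <- scan_motif(c(x = "GGCGGAAACGCC"), pat)
  # reference identical to the hit: stem GGCG paired by C,G,C,C (per column)
  ref_same <- data.frame(base5 = c("G", "G", "C", "G"),
                         base3 = c("C", "C", "G", "C"))
  r1 <- compare_to_reference(h, ref_same)
  expect_identical(c(r1$n_identical, r1$n_compensatory), c(4L, 0L))
  # column 1 pairs A:T in the reference instead of G:C -> compensatory
  ref_comp <- ref_same; ref_comp$base5[1] <- "A"; ref_comp$base3[1] <- "T"
  r2 <- compare_to_reference(h, ref_comp)
  expect_identical(c(r2$n_identical, r2$n_compensatory), c(3L, 1L))
  # a non-pairing reference column counts as neither
  ref_mis <- ref_same; ref_mis$base3[2] <- "A"   # G:A does not pair
  r3 <- compare_to_reference(h, ref_mis)
  expect_identical(c(r3$n_identical, r3$n_compensatory), c(3L, 0L))
  expect_error(compare_to_reference(h, ref_same[1:2, ]), "columns")
})

test_that("motif pattern files parse to the same pattern", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# 530-loop-like hairpin", "stem_open s1 4",
               "literal GAAA 0", "stem_close s1 0 gu"), f)
  pat <- parse_motif_pattern(f)
  h <- scan_motif(c(x = "GGCGGAAACGCC"), pat)
  expect_identical(nrow(h$hits), 1L)
})
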
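test_that("percent expansion follows the exact identity", {
  # gene of length 100 carrying 80 inserted and 4 deleted U's -> 76% longer
  set.seed(10)
  mt <- simulate_mt(sim_params(seed = 10, n_genes = 6L))
  mats <- c(mt$mrnas, mt$rrnas)
  for (g in mt$truth$genes$gene_id) {
    st <- summarize_editing(align_editing(mt$gene_seqs[g], mats[g]))
    expect_identical(st$pct_expansion,
                     100 * (st$n_ins - st$n_del) / st$gene_len)
  }
  # the arithmetic itself, at the printed magnitudes
  expect_identical(100 * (80 - 4) / 100, 76)
  expect_identical(100 * (885 - 0) / 1000, 88.5)
})

test_that("editing patterns are classified from binned site density", {
  ev <- function(pos) data.frame(kind = rep("U_INS", length(pos)),
                                 gene_pos = pos, mrna_pos = pos,
                                 run_len = rep(1L, length(pos)))
  # sites across 90% of the gene
  expect_identical(classify_pattern(ev(seq(5, 95, by = 5)), 100), "PAN")
  # sites confined to bins 0-3 of 20
  expect_identical(classify_pattern(ev(c(2, 6, 11, 16)), 100), "FIVE_PRIME")
  # sites in bins 0-2 and 18-19 (terminal editing at both ends)
  expect_identical(classify_pattern(ev(c(2, 7, 12, 91, 96)), 100),
                   "FIVE_AND_THREE_PRIME")
  # fewer than 3 sites
  expect_identical(classify_pattern(ev(c(10, 50)), 100), "UNEDITED")
  expect_identical(classify_pattern(ev(integer(0)), 100), "UNEDITED")
  expect_error(classify_pattern(ev(1), 0), "gene_len")
})

test_that("deaminative clusters match a brute-force windowing oracle", {
  # the 12-edit / 30-nt configuration: 8 C-to-U + 4 A-to-I
  set.seed(12)
  pos <- sort(sample(100:129, 12))
  ev <- data.frame(kind = c(rep("C_TO_U", 8), rep("A_TO_I", 4)),
                   gene_pos = pos, mrna_pos = pos, run_len = 1L)
  cl <- detect_deaminative_clusters(ev, window = 30L, min_edits = 3L)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_edits, 12L)
  expect_identical(cl$n_c_to_u, 8L)
  expect_identical(cl$n_a_to_i, 4L)
  expect_lte(cl$end - cl$start, 30L)

  expect_identical(nrow(detect_deaminative_clusters(ev[0, ], 30, 3)), 0L)
  far <- data.frame(kind = c("C_TO_U", "C_TO_U"), gene_pos = c(0L, 100L),
                    mrna_pos = c(0L, 100L), run_len = 1L)
  expect_identical(nrow(detect_deaminative_clusters(far, 30, 3)), 0L)

  # equivalence with the brute-force oracle on random instances
  for (i in 1:25) {
    n <- sample(3:15, 1)
    pos <- sort(sample(0:300, n))
    ev <- data.frame(kind = sample(c("C_TO_U", "A_TO_I"), n, replace = TRUE),
                     gene_pos = pos, mrna_pos = pos, run_len = 1L)
    w <- sample(5:50, 1); m <- sample(2:4, 1)
    got <- detect_deaminative_clusters(ev, w, m)
    want <- brute_clusters(ev, w, m)
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      expect_identical(got$n_edits, vapply(want, length, 0L))
      expect_identical(got$start, vapply(want, min, 0L))
    }
  }
})

test_that("stop-codon provenance distinguishes editing-created stops", {
  pg <- edit_align_params(end_free_gene = FALSE)
  # gene ...AA -> mRNA ...TAA via a U insertion: stop contains the inserted U
  a <- align_editing(c(g = "ATGCCCAA"), c(m = "ATGCCCTAA"), pg)
  expect_identical(a$events$kind, "U_INS")
  expect_true(stop_created_by_editing(a, code = "4"))

  # unedited TAA: stop present in the gene itself
  b <- align_editing(c(g = "ATGCCCTAA"), c(m = "ATGCCCTAA"), pg)
  expect_false(stop_created_by_editing(b, code = "4"))

  # TGA is tryptophan under code 4: no stop found -> FALSE with a warning
  cc <- align_editing(c(g = "ATGCCCTGA"), c(m = "ATGCCCTGA"), pg)
  expect_warning(res <- stop_created_by_editing(cc, code = "4"), "no in-frame stop")
  expect_false(res)
  # ... but a genuine stop under the standard code
  expect_false(stop_created_by_editing(cc, code = "1"))

  expect_error(stop_created_by_editing(b, code = "999"), "unknown genetic code")
})

test_that("species summaries aggregate per-gene statistics correctly", {
  st <- data.frame(n_ins = c(100L, 200L), n_del = c(10L, 30L),
                   pct_expansion = c(45, 85))
  agg <- aggregate_editing(st)
  expect_identical(agg$mean_ins, 150)
  expect_identical(c(agg$min_ins, agg$max_ins), c(100L, 200L))
  expect_identical(agg$mean_del, 20)
  # invariance under reordering
  expect_identical(aggregate_editing(st[2:1, ]), agg)
  one <- aggregate_editing(st[1, ])
  expect_identical(one$mean_ins, one$min_ins + 0)
  expect_error(aggregate_editing(st[0, ]), "empty")
})
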
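p_glob <- edit_align_params(end_free_gene = FALSE)

test_that("constrained alignment emits the expected canonical events", {
  a0 <- align_editing(c(g = "ACG"), c(m = "ACG"), p_glob)
  expect_identical(nrow(a0$events), 0L)
  expect_identical(c(a0$n_ins, a0$n_del), c(0L, 0L))
  expect_equal(a0$score, 3 * p_glob$match)

  a1 <- align_editing(c(g = "AG"), c(m = "ATTG"), p_glob)
  expect_identical(a1$events$kind, "U_INS")
  expect_identical(a1$events$gene_pos, 1L)
  expect_identical(a1$events$run_len, 2L)
  expect_equal(a1$score, 2 * p_glob$match + p_glob$ins_open + p_glob$ins_ext)

  a2 <- align_editing(c(g = "ATG"), c(m = "AG"), p_glob)
  expect_identical(a2$events$kind, "U_DEL")
  expect_identical(a2$events$gene_pos, 1L)

  a3 <- align_editing(c(g = "ACA"), c(m = "ATA"), p_glob)
  expect_identical(a3$events$kind, "C_TO_U")
  expect_identical(a3$events$gene_pos, 1L)

  a4 <- align_editing(c(g = "AAG"), c(m = "AGG"), p_glob)
  expect_identical(a4$events$kind, "A_TO_I")
})

test_that("incompatible sequences yield an explicit unalignable result", {
  p <- edit_align_params(allow_other_mismatch = FALSE, end_free_gene = FALSE)
  u <- align_editing(c(g = "AAA"), c(m = "CCC"), p)
  expect_true(u$unalignable)
  expect_identical(nrow(u$events), 0L)
})

test_that("oracle enumeration matches its closed-form spot checks", {
  p <- edit_align_params()
  expect_equal(oracle_align("ACG", "ACG", p), 3 * p$match)
  expect_equal(oracle_align("AG", "ATTG", p), 2 * p$match + p$ins_open + p$ins_ext)
  expect_error(oracle_align(random_dna(11), "ACG"), "size limit")
})

test_that("DP score equals exhaustive oracle score on random admissible pairs", {
  set.seed(1)
  for (i in 1:200) {
    pr <- random_edit_pair()
    for (p in list(edit_align_params(), p_glob)) {
      o <- oracle_align(pr$gene, pr$mrna, p)
      a <- align_editing(c(g = pr$gene), c(m = pr$mrna), p)
      s <- if (isTRUE(a$unalignable)) -Inf else a$score
      expect_equal(s, o, info = paste(pr$gene, pr$mrna))
    }
  }
})

test_that("length conservation and reconstruction round trip hold", {
  set.seed(2)
  mt <- simulate_mt(sim_params(seed = 77, n_genes = 4L))
  mats <- c(mt$mrnas, mt$rrnas)
  for (g in mt$truth$genes$gene_id) {
    a <- align_editing(mt$gene_seqs[g], mats[g])
    glen <- a$gene_ival$end - a$gene_ival$start
    expect_identical(nchar(mats[[g]]), glen + a$n_ins - a$n_del)
    rec <- apply_edit_events(mt$gene_seqs[[g]], a$events, a$gene_ival,
                             a$mismatches)
    expect_identical(rec, mats[[g]])
  }
})

test_that("indel runs are left-shifted to their canonical placement", {
  # one deletion in a TT homopolymer: two score-equal placements, left chosen
  a <- align_editing(c(g = "TT"), c(m = "T"), p_glob)
  expect_identical(a$events$kind, "U_DEL")
  expect_identical(a$events$gene_pos, 0L)

  # insertion next to an existing T: run reported at the leftmost position
  b <- align_editing(c(g = "ATC"), c(m = "ATTTC"), p_glob)
  expect_identical(b$events$kind, "U_INS")
  expect_identical(b$events$gene_pos, 1L)
  expect_identical(b$events$run_len, 2L)

  # canonicalize is idempotent
  expect_identical(canonicalize(b)$events, b$events)
})

test_that("a forced extra U insertion increases n_ins by exactly one", {
  set.seed(3)
  for (i in 1:20) {
    g <- paste0("C", random_dna(20), "C")  # non-T anchors
    a <- align_editing(c(g = g), c(m = g), p_glob)
    base <- a$n_ins
    # insert one U at a position whose neighbours are not T
    ch <- strsplit(g, "", fixed = TRUE)[[1L]]
    pos <- which(ch != "T" & c("X", utils::head(ch, -1)) != "T")
    p <- sample(pos[pos > 1], 1L)
    m2 <- paste0(substr(g, 1, p - 1), "T", substr(g, p, nchar(g)))
    a2 <- align_editing(c(g = g), c(m = m2), p_glob)
    expect_identical(a2$n_ins, base + 1L)
    expect_identical(a2$n_del, a$n_del)
  }
})

test_that("semi-global mode aligns a transcript to a padded gene region", {
  set.seed(6)
  core <- random_dna(60)
  gene_region <- paste0(random_dna(25), core, random_dna(25))
  a <- align_editing(c(g = gene_region), c(m = core))
  expect_false(a$unalignable)
  expect_identical(c(a$gene_ival$start, a$gene_ival$end), c(25L, 85L))
  expect_identical(nrow(a$events), 0L)
})
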
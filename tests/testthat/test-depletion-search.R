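test_that("deplete_t projects T's out and keeps an exact coordinate map", {
  d <- deplete_t(c(x = "ATTACGT"))
  expect_identical(d$depleted, "AACG")
  expect_identical(d$index_map, c(0L, 3L, 4L, 5L))

  # the printed SL-region string
  d2 <- deplete_t("TTACAGTTTCTGTACTT")
  expect_identical(d2$depleted, "ACAGCGAC")
  expect_identical(d2$index_map, c(2L, 3L, 4L, 5L, 9L, 11L, 13L, 14L))

  d3 <- deplete_t("TTTT")
  expect_identical(d3$depleted, "")
  expect_identical(d3$index_map, integer(0))

  # projection: on a T-free string depletion is the identity
  set.seed(4)
  s <- gsub("T", "A", random_dna(200))
  d4 <- deplete_t(s)
  expect_identical(d4$depleted, s)
  expect_identical(d4$index_map, 0:(nchar(s) - 1L))
})

test_that("restore_interval maps depleted bounds back to original coordinates", {
  d <- deplete_t(c(x = "ATTACGT"))
  iv <- restore_interval(d, 1, 3)
  expect_identical(c(iv$start, iv$end), c(3L, 5L))
  iv0 <- restore_interval(d, 0, 1)
  expect_identical(c(iv0$start, iv0$end), c(0L, 1L))
  expect_error(restore_interval(d, 0, 5), "out of range")

  # substring consistency: the depleted substring of a restored interval
  # equals the slice of the depleted string
  set.seed(5)
  for (rep in 1:20) {
    s <- random_dna(100)
    dd <- deplete_t(s)
    n <- nchar(dd$depleted)
    if (n < 2) next
    a <- sample(0:(n - 2L), 1L); b <- sample((a + 1L):n, 1L)
    iv <- restore_interval(dd, a, b)
    sub <- substr(s, iv$start + 1L, iv$end)
    expect_identical(deplete_t(sub)$depleted,
                     substr(dd$depleted, a + 1L, b))
  }
})

test_that("tdepleted_search locates a planted cryptogene under any U-indel pattern", {
  set.seed(42)
  gene <- random_dna(300)
  contig <- paste0(random_dna(900), gene, random_dna(800))
  db <- c(ctg = contig)

  # arbitrary U insertions/deletions are invisible in depleted space
  for (rep in 1:5) {
    ch <- strsplit(gene, "", fixed = TRUE)[[1L]]
    ins_at <- sort(sample(seq_along(ch), 40), decreasing = TRUE)
    for (p in ins_at) ch <- append(ch, rep("T", sample(1:3, 1)), after = p)
    ts <- which(ch == "T")
    ch <- ch[-sample(ts, min(5, length(ts)))]
    mrna <- paste0(ch, collapse = "")
    h <- tdepleted_search(c(m = mrna), db)
    expect_gt(nrow(h), 0)
    expect_equal(h$s_start[1], 900, tolerance = 0, ignore_attr = TRUE)
    expect_lte(abs(h$s_end[1] - 1200), 5)
    expect_gte(h$identity[1], 0.95)
  }

  # the unedited gene itself: full-identity hit (restored bounds land on the
  # outermost non-T characters, so allow a few nt of slack at the edges)
  h0 <- tdepleted_search(c(g = gene), db)
  expect_equal(h0$identity[1], 1.0)
  expect_lte(abs(h0$s_start[1] - 900L), 5L)
  expect_lte(abs(h0$s_end[1] - 1200L), 5L)

  # unrelated random query: nothing above threshold
  hneg <- tdepleted_search(c(r = random_dna(300)), db,
                           search_params(seed_len = 10L, min_hit_len = 50L,
                                         min_identity = 0.8))
  expect_identical(nrow(hneg), 0L)
})

test_that("local_search reports identity over alignment columns and both strands", {
  set.seed(7)
  db <- c(ctg = random_dna(2000))
  q <- substr(db[[1]], 501, 700)
  h <- local_search(c(q = q), db)
  expect_identical(c(h$s_start[1], h$s_end[1]), c(500L, 700L))
  expect_equal(h$identity[1], 1.0)
  expect_identical(h$strand[1], "+")

  # 5% substitutions over 200 nt
  qm <- mutate_at(q, round(seq(10, 190, length.out = 10)))
  hm <- local_search(c(qm = qm), db)
  expect_gte(hm$identity[1], 0.93)
  expect_lte(hm$identity[1], 0.97)

  hr <- local_search(c(qr = revcomp(q)), db)
  expect_identical(hr$strand[1], "-")
  expect_identical(c(hr$s_start[1], hr$s_end[1]), c(500L, 700L))

  expect_identical(nrow(local_search(c(q = q), character(0))), 0L)
})
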
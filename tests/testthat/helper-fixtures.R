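# shared fixture builders (all in-code; no data files)

# substitute the characters at `pos` (1-based) deterministically
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[[1L]]
  paste0(ch, collapse = "")
}

# a contig with `seg` embedded between random flanks
embed_segment <- function(seg, flank = 400L, id = "ctg") {
  setNames(paste0(random_dna(flank), seg, random_dna(flank)), id)
}

# random (gene, mRNA) pair linked by <= max_ops admissible edit operations;
# sizes stay within the oracle limits (gene <= 8, mRNA <= 12)
random_edit_pair <- function(max_ops = 4L) {
  repeat {
    g <- random_dna(sample(4:8, 1L))
    m <- g
    ok <- TRUE
    for (k in seq_len(sample(0:max_ops, 1L))) {
      ch <- strsplit(m, "", fixed = TRUE)[[1L]]
      op <- sample(c("ins", "del", "sub"), 1L)
      if (op == "ins") {
        p <- sample(0:length(ch), 1L)
        ch <- append(ch, rep("T", sample(1:2, 1L)), after = p)
      } else if (op == "del") {
        ts <- which(ch == "T")
        if (length(ts)) ch <- ch[-sample(ts, 1L)]
      } else {
        p <- sample(seq_along(ch), 1L)
        ch[p] <- sample(c("A", "C", "G", "T"), 1L)
      }
      m <- paste0(ch, collapse = "")
      if (nchar(m) > 12L || nchar(m) < 1L) { ok <- FALSE; break }
    }
    if (ok) return(list(gene = g, mrna = m))
  }
}

# brute-force maximal-window clustering of substitution events (oracle for
# detect_deaminative_clusters)
brute_clusters <- function(events, window, min_edits) {
  subs <- events[events$kind %in% c("C_TO_U", "A_TO_I"), , drop = FALSE]
  if (nrow(subs) == 0) return(list())
  pos <- sort(subs$gene_pos)
  groups <- list(); cur <- pos[[1L]]
  for (p in pos[-1L]) {
    if (p - cur[[length(cur)]] <= window) cur <- c(cur, p)
    else { groups[[length(groups) + 1L]] <- cur; cur <- p }
  }
  groups[[length(groups) + 1L]] <- cur
  Filter(function(g) length(g) >= min_edits, groups)
}
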
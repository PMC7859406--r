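#' @title U-indel editing alignment
#' @description Align a (crypto)gene region to its mature mRNA permitting only
#'   U insertions (gaps in the gene opposite mRNA T's), U deletions (gaps in
#'   the mRNA opposite gene T's), deaminative substitutions (gene C vs mRNA T
#'   = C-to-U; gene A vs mRNA G = A-to-I, observed in cDNA as A-to-G), and —
#'   optionally — other mismatches to tolerate sequencing error. The optimum
#'   is computed by an affine three-state dynamic program; indel runs are
#'   canonicalized to their leftmost (5'-most) score-equal placement.
#' @name editing_alignment
NULL

#' Scoring parameters for editing alignment
#'
#' Defaults recover simulated edit patterns exactly at the editing densities
#' seen in pan-edited kinetoplastid mRNAs: matches reward +2, deaminative
#' substitutions cost less than any indel explanation of a single site, other
#' mismatches are strongly penalized but allowed (sequencing error), and run
#' extension is cheap relative to run opening, reflecting the long U-insertion
#' runs of pan-editing. A run of length L costs `open + (L - 1) * ext`.
#'
#' @param match diagonal match reward (> 0)
#' @param deam_sub penalty for a C-to-U or A-to-I substitution (< 0)
#' @param other_mismatch penalty for any other diagonal pairing (< 0)
#' @param allow_other_mismatch if FALSE, only the canonical edit operations are
#'   admissible and incompatible pairs make the alignment "unalignable"
#' @param ins_open,ins_ext U-insertion run open/extend penalties (< 0)
#' @param del_open,del_ext U-deletion run open/extend penalties (< 0)
#' @param end_free_gene if TRUE (default), leading/trailing gene characters are
#'   skipped free of charge, so a transcript may cover a sub-region of the
#'   provided (padded) gene interval; the mRNA is always aligned end to end
#' @return list of class `edit_align_params`
#' @export
edit_align_params <- function(match = 2, deam_sub = -4, other_mismatch = -9,
                              allow_other_mismatch = TRUE,
                              ins_open = -3, ins_ext = -1,
                              del_open = -3, del_ext = -1,
                              end_free_gene = TRUE) {
  stopifnot(match > 0, deam_sub < 0, other_mismatch < 0,
            ins_open < 0, ins_ext < 0, del_open < 0, del_ext < 0)
  structure(list(match = match, deam_sub = deam_sub,
                 other_mismatch = other_mismatch,
                 allow_other_mismatch = isTRUE(allow_other_mismatch),
                 ins_open = ins_open, ins_ext = ins_ext,
                 del_open = del_open, del_ext = del_ext,
                 end_free_gene = isTRUE(end_free_gene)),
            class = "edit_align_params")
}

.empty_events <- function() {
  data.frame(kind = character(0), gene_pos = integer(0),
             mrna_pos = integer(0), run_len = integer(0),
             stringsAsFactors = FALSE)
}

# left-shift every gap block to its 5'-most score-equal admissible placement
# (homopolymer normalization). grow/mrow are character vectors of the aligned
# (gapped) rows; returns the normalized rows.
.left_shift_gaps <- function(grow, mrow) {
  ncol <- length(grow)
  repeat {
    moved <- FALSE
    col <- 2L
    while (col <= ncol) {
      if (grow[col] == "-") {            # insertion block (gap in gene)
        b0 <- col
        while (col <= ncol && grow[col] == "-") col <- col + 1L
        b1 <- col - 1L
        # shift while preceding column is diagonal and its mRNA char is T
        while (b0 > 1L && grow[b0 - 1L] != "-" && mrow[b0 - 1L] == "T") {
          # swap column b0-1 with block: gene char moves to b1
          grow[b1] <- grow[b0 - 1L]; grow[b0 - 1L] <- "-"
          # mRNA chars: all T within block and at b0-1; unchanged by the swap
          b0 <- b0 - 1L; b1 <- b1 - 1L
          moved <- TRUE
        }
      } else if (mrow[col] == "-") {     # deletion block (gap in mRNA)
        b0 <- col
        while (col <= ncol && grow[col] != "-" && mrow[col] == "-") col <- col + 1L
        b1 <- col - 1L
        while (b0 > 1L && mrow[b0 - 1L] != "-" && grow[b0 - 1L] == "T") {
          mrow[b1] <- mrow[b0 - 1L]; mrow[b0 - 1L] <- "-"
          b0 <- b0 - 1L; b1 <- b1 - 1L
          moved <- TRUE
        }
      } else {
        col <- col + 1L
      }
    }
    if (!moved) break
  }
  list(grow = grow, mrow = mrow)
}

# derive the canonical event list from gapped rows; gene_off is the 0-based
# original position of the first aligned gene character
.events_from_rows <- function(grow, mrow, gene_off) {
  events <- list(); mism <- list()
  gi <- gene_off; mi <- 0L
  col <- 1L; ncol <- length(grow)
  while (col <= ncol) {
    if (grow[col] == "-") {
      run <- 0L; m0 <- mi
      while (col <= ncol && grow[col] == "-") { run <- run + 1L; mi <- mi + 1L; col <- col + 1L }
      events[[length(events) + 1L]] <- list(kind = "U_INS", gene_pos = gi,
                                            mrna_pos = m0, run_len = run)
    } else if (mrow[col] == "-") {
      run <- 0L; g0 <- gi
      while (col <= ncol && grow[col] != "-" && mrow[col] == "-") {
        run <- run + 1L; gi <- gi + 1L; col <- col + 1L
      }
      events[[length(events) + 1L]] <- list(kind = "U_DEL", gene_pos = g0,
                                            mrna_pos = mi, run_len = run)
    } else {
      g <- grow[col]; c <- mrow[col]
      if (g != c) {
        if (g == "C" && c == "T") {
          events[[length(events) + 1L]] <- list(kind = "C_TO_U", gene_pos = gi,
                                                mrna_pos = mi, run_len = 1L)
        } else if (g == "A" && c == "G") {
          events[[length(events) + 1L]] <- list(kind = "A_TO_I", gene_pos = gi,
                                                mrna_pos = mi, run_len = 1L)
        } else {
          mism[[length(mism) + 1L]] <- list(gene_pos = gi, mrna_pos = mi,
                                            gene_char = g, mrna_char = c)
        }
      }
      gi <- gi + 1L; mi <- mi + 1L; col <- col + 1L
    }
  }
  ev <- if (length(events)) {
    do.call(rbind, lapply(events, as.data.frame, stringsAsFactors = FALSE))
  } else .empty_events()
  mm <- if (length(mism)) {
    do.call(rbind, lapply(mism, as.data.frame, stringsAsFactors = FALSE))
  } else data.frame(gene_pos = integer(0), mrna_pos = integer(0),
                    gene_char = character(0), mrna_char = character(0),
                    stringsAsFactors = FALSE)
  ev <- ev[order(ev$gene_pos, ev$mrna_pos), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, mismatches = mm)
}

#' Align a gene region to a mature mRNA under the editing operation set
#'
#' @param gene_region length-1 named character vector (cryptogene region, DNA)
#' @param mrna length-1 named character vector (mature transcript, U stored
#'   as T)
#' @param params an [edit_align_params()]
#' @param gene_offset 0-based position of the first `gene_region` character on
#'   its source sequence; reported `gene_ival`/event positions are shifted by
#'   this, so events can be reported in contig coordinates
#' @return object of class `editing_alignment`: list with gene_id, mrna_id,
#'   gene_ival (0-based half-open aligned gene span), events (data.frame kind,
#'   gene_pos, mrna_pos, run_len), mismatches (tolerated non-deaminative
#'   diagonal pairs), score, n_ins, n_del, unalignable flag and the gapped
#'   rows. If no admissible alignment exists the object has
#'   `unalignable = TRUE` and empty events.
#' @export
align_editing <- function(gene_region, mrna, params = edit_align_params(),
                          gene_offset = 0L) {
  gid <- if (!is.null(names(gene_region))) names(gene_region)[[1L]] else "gene"
  mid <- if (!is.null(names(mrna))) names(mrna)[[1L]] else "mrna"
  g <- toupper(as.character(gene_region[[1L]]))
  m <- toupper(as.character(mrna[[1L]]))
  if (is.na(g) || is.na(m) || !nzchar(g) || !nzchar(m)) {
    stop("align_editing: empty or missing sequence")
  }
  res <- .editing_dp(g, m, params$match, params$deam_sub, params$other_mismatch,
                     params$allow_other_mismatch,
                     params$ins_open, params$ins_ext,
                     params$del_open, params$del_ext, params$end_free_gene)
  if (isTRUE(res$unalignable)) {
    return(structure(list(gene_id = gid, mrna_id = mid, gene_ival = NULL,
                          events = .empty_events(),
                          mismatches = NULL, score = NA_real_,
                          n_ins = NA_integer_, n_del = NA_integer_,
                          unalignable = TRUE, gene_row = NULL, mrna_row = NULL,
                          gene_offset = gene_offset, params = params),
                     class = "editing_alignment"))
  }
  ops <- strsplit(res$ops, "", fixed = TRUE)[[1L]]
  gc <- strsplit(g, "", fixed = TRUE)[[1L]]
  mc <- strsplit(m, "", fixed = TRUE)[[1L]]
  gi <- res$gene_start; mi <- 0L
  grow <- character(length(ops)); mrow <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == "M") {
      gi <- gi + 1L; mi <- mi + 1L
      grow[k] <- gc[gi]; mrow[k] <- mc[mi]
    } else if (ops[k] == "I") {
      mi <- mi + 1L
      grow[k] <- "-"; mrow[k] <- mc[mi]
    } else {
      gi <- gi + 1L
      grow[k] <- gc[gi]; mrow[k] <- "-"
    }
  }
  shifted <- .left_shift_gaps(grow, mrow)
  evs <- .events_from_rows(shifted$grow, shifted$mrow,
                           res$gene_start + gene_offset)
  n_ins <- sum(evs$events$run_len[evs$events$kind == "U_INS"])
  n_del <- sum(evs$events$run_len[evs$events$kind == "U_DEL"])
  structure(list(gene_id = gid, mrna_id = mid,
                 gene_ival = interval(gid, res$gene_start + gene_offset,
                                      res$gene_end + gene_offset),
                 events = evs$events, mismatches = evs$mismatches,
                 score = res$score,
                 n_ins = as.integer(n_ins), n_del = as.integer(n_del),
                 unalignable = FALSE,
                 gene_row = paste0(shifted$grow, collapse = ""),
                 mrna_row = paste0(shifted$mrow, collapse = ""),
                 gene_offset = gene_offset, params = params),
            class = "editing_alignment")
}

#' Canonicalize an editing alignment
#'
#' Shifts every indel run to its 5'-most (leftmost) score-equal admissible
#' placement and re-derives the event list. [align_editing()] already returns
#' canonical alignments; this is idempotent.
#'
#' @param aln an `editing_alignment`
#' @return the canonicalized `editing_alignment`
#' @export
canonicalize <- function(aln) {
  stopifnot(inherits(aln, "editing_alignment"))
  if (isTRUE(aln$unalignable)) return(aln)
  grow <- strsplit(aln$gene_row, "", fixed = TRUE)[[1L]]
  mrow <- strsplit(aln$mrna_row, "", fixed = TRUE)[[1L]]
  shifted <- .left_shift_gaps(grow, mrow)
  evs <- .events_from_rows(shifted$grow, shifted$mrow, aln$gene_ival$start)
  aln$events <- evs$events
  aln$mismatches <- evs$mismatches
  aln$gene_row <- paste0(shifted$grow, collapse = "")
  aln$mrna_row <- paste0(shifted$mrow, collapse = "")
  aln
}

#' Apply edit events to a gene region, reconstructing the mature mRNA
#'
#' Inserts U's (as T), deletes gene T's and applies substitutions as recorded
#' in an alignment's event (and tolerated-mismatch) tables. Round trip:
#' applying the events of `align_editing(gene, mrna)` to the aligned gene span
#' reproduces `mrna` exactly.
#'
#' @param gene character scalar, the FULL source sequence the event
#'   coordinates refer to
#' @param events event data.frame (kind, gene_pos, mrna_pos, run_len)
#' @param gene_ival aligned gene span as returned in the alignment (data.frame
#'   with start/end); defaults to the whole of `gene`
#' @param mismatches optional tolerated-mismatch table (gene_pos, mrna_char)
#' @return reconstructed mRNA string
#' @export
apply_edit_events <- function(gene, events, gene_ival = NULL, mismatches = NULL) {
  g <- toupper(as.character(gene[[1L]]))
  lo <- if (is.null(gene_ival)) 0L else gene_ival$start
  hi <- if (is.null(gene_ival)) nchar(g) else gene_ival$end
  gc <- strsplit(g, "", fixed = TRUE)[[1L]]
  out <- character(0)
  ev <- events[order(events$gene_pos, events$mrna_pos), , drop = FALSE]
  subs <- character(0)
  if (!is.null(mismatches) && nrow(mismatches)) {
    subs <- setNames(mismatches$mrna_char, as.character(mismatches$gene_pos))
  }
  pos <- lo  # 0-based cursor on the gene
  r <- 1L
  while (pos < hi || r <= nrow(ev)) {
    if (r <= nrow(ev) && ev$gene_pos[r] == pos && ev$kind[r] == "U_INS") {
      out <- c(out, rep("T", ev$run_len[r])); r <- r + 1L
      next
    }
    if (pos >= hi) break
    if (r <= nrow(ev) && ev$gene_pos[r] == pos && ev$kind[r] == "U_DEL") {
      if (any(gc[(pos + 1L):(pos + ev$run_len[r])] != "T")) {
        stop("U_DEL event at gene_pos ", pos, " does not cover T characters")
      }
      pos <- pos + ev$run_len[r]; r <- r + 1L
      next
    }
    ch <- gc[pos + 1L]
    if (r <= nrow(ev) && ev$gene_pos[r] == pos) {
      ch <- switch(ev$kind[r], C_TO_U = "T", A_TO_I = "G",
                   stop("unexpected event kind ", ev$kind[r]))
      r <- r + 1L
    } else if (as.character(pos) %in% names(subs)) {
      ch <- subs[[as.character(pos)]]
    }
    out <- c(out, ch)
    pos <- pos + 1L
  }
  paste0(out, collapse = "")
}

#' Exhaustive oracle for the editing alignment score
#'
#' Enumerates every admissible alignment path (diagonal, U-insertion,
#' U-deletion moves under the same constraints and affine run costs as
#' [align_editing()]) by memo-free recursion and returns the maximum score.
#' Intended as an independent test oracle on tiny inputs.
#'
#' @inheritParams align_editing
#' @return the optimal score (`-Inf` when no admissible alignment exists)
#' @export
oracle_align <- function(gene_region, mrna, params = edit_align_params()) {
  g <- strsplit(toupper(as.character(gene_region[[1L]])), "", fixed = TRUE)[[1L]]
  m <- strsplit(toupper(as.character(mrna[[1L]])), "", fixed = TRUE)[[1L]]
  if (length(g) > 10L || length(m) > 12L) {
    stop("oracle_align: size limit exceeded (gene <= 10, mrna <= 12)")
  }
  n <- length(g); mm <- length(m)
  pair <- function(gc, mc) {
    if (gc == mc && gc != "N") return(params$match)
    if (gc == "C" && mc == "T") return(params$deam_sub)
    if (gc == "A" && mc == "G") return(params$deam_sub)
    if (params$allow_other_mismatch) return(params$other_mismatch)
    -Inf
  }
  rec <- function(i, j, state) {
    best <- -Inf
    if (j == mm) {
      if (i == n || params$end_free_gene) best <- 0
      # a deletion run may still consume trailing gene T's
      if (i < n && g[i + 1L] == "T") {
        cost <- if (state == "D") params$del_ext else params$del_open
        best <- max(best, cost + rec(i + 1L, mm, "D"))
      }
      return(best)
    }
    if (i < n) {
      ps <- pair(g[i + 1L], m[j + 1L])
      if (is.finite(ps)) best <- max(best, ps + rec(i + 1L, j + 1L, "M"))
    }
    if (m[j + 1L] == "T") {
      cost <- if (state == "I") params$ins_ext else params$ins_open
      best <- max(best, cost + rec(i, j + 1L, "I"))
    }
    if (i < n && g[i + 1L] == "T") {
      cost <- if (state == "D") params$del_ext else params$del_open
      best <- max(best, cost + rec(i + 1L, j, "D"))
    }
    best
  }
  starts <- if (params$end_free_gene) 0:n else 0L
  max(vapply(starts, function(i0) rec(i0, 0L, "start"), numeric(1)))
}

#' @export
print.editing_alignment <- function(x, ...) {
  if (isTRUE(x$unalignable)) {
    cat(sprintf("<editing_alignment %s ~ %s: unalignable>\n", x$gene_id, x$mrna_id))
  } else {
    cat(sprintf(
      "<editing_alignment %s ~ %s: score %.1f, %d U ins, %d U del, %d deam subs, gene [%d,%d)>\n",
      x$gene_id, x$mrna_id, x$score, x$n_ins, x$n_del,
      sum(x$events$kind %in% c("C_TO_U", "A_TO_I")),
      x$gene_ival$start, x$gene_ival$end))
  }
  invisible(x)
}
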
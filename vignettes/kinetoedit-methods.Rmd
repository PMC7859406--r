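---
title: "Reconstructing kinetoplastid U-indel RNA editing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing kinetoplastid U-indel RNA editing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetoedit)
```

## The problem

Kinetoplastid mitochondria rewrite their transcripts after transcription:
guide-RNA directed machinery inserts and deletes uridines (U-indel editing),
in the most extreme cases along the whole transcript ("pan-editing"). The
genes encoding such transcripts — cryptogenes — are unrecognizable by ordinary
sequence search, because most of the mature mRNA consists of U's that are
absent from the DNA. A genome/transcriptome study of such an organism
therefore needs a small set of specialised computations:

* find cryptogenes despite the editing (thymidine-depleted homology search);
* align each cryptogene to its mature mRNA under the *constrained* operation
  set of the biology (U insertion, U deletion, C-to-U and A-to-I deamination)
  and count the events;
* identify minicircles and their guide-RNA (gRNA) cassettes, which pair
  antisense with edited mRNA using Watson-Crick *and G:U wobble* pairs;
* detect spliced-leader (SL) sequences on nuclear transcripts, separate prey
  contamination from target sequence, and quantify the polycistron-like
  same-strand gene clustering typical of the group.

`kinetoedit` implements this toolkit, plus a seeded simulator
(`simulate_bundle()`) that generates data with the same statistical structure
and complete ground truth, so that every step can be tested by exact
parameter recovery. The `analysis/` scripts run the whole workflow on
simulated data and write their tables under `results/`.

## T-depletion search

`deplete_t()` removes every T from a sequence and keeps an index map back to
the original coordinates; `tdepleted_search()` runs a seed-and-extend local
search in this 3-letter space, on both strands of the database (the subject is
reverse-complemented, never the query), with no low-complexity masking.
Because U-indel editing only adds or removes T's, a cryptogene and its mature
mRNA project to (near-)identical depleted strings, so any pattern of U-indels
is invisible to the search — the property the whole approach rests on, and one
of the package's property tests.

The searcher seeds on exact k-mers (default 10 in depleted space, 12 in
standard space; smaller seeds down to 4 are supported at a sensitivity/speed
cost), chains seeds by diagonal, extends the modal diagonal ungapped with an
x-drop rule, and refines gapped alignment only for clusters whose ungapped
anchor score passes a small gate (2k + 6). Gapped refinement and coordinate
bookkeeping use `Biostrings::pairwiseAlignment` on a window padded by the band
(15 nt). Identity is always matches / alignment columns, gaps included, and
N matches nothing. Anchoring on the modal diagonal assumes the true alignment
is locally ungapped, which holds in depleted space (editing vanishes) and for
the substitution-only divergences this package is used on; heavily gapped
standard-space homology would need a different tool.

## The editing alignment

`align_editing()` is the package's core: an affine three-state dynamic program
(match / insertion-run / deletion-run) over gene x mRNA in which

* a gap in the gene (U insertion) is admissible only where the mRNA character
  is T;
* a gap in the mRNA (U deletion) is admissible only where the gene character
  is T;
* gene C vs mRNA T is a C-to-U edit, gene A vs mRNA G an A-to-I edit (recorded
  from the observable A-to-G change in cDNA);
* any other pairing is a heavily penalized "other mismatch", kept admissible
  by default so that sequencing errors do not break an alignment, but
  excluded from the edit-event vocabulary (such columns are reported in a
  separate `mismatches` table).

Default scores are match +2, deaminative substitution -4, other mismatch -9,
run open -3, run extension -1 (a run of length L costs open + (L-1)·ext).
Extension is cheap relative to opening because pan-editing inserts U's in
runs; a single deaminative substitution (-4) is preferred to the cheapest
indel pair explanation (-6) and other-mismatch (-9), so isolated
C-to-U/A-to-I sites are recovered as substitutions. The DP is O(n·m) with two
rolling score rows and full traceback matrices, implemented in C++; mt genes
are ≤ ~2 kb, so full DP is desk-scale (a 1 kb x 2 kb pair aligns in well
under a second).

Semi-global mode (`end_free_gene = TRUE`, the default) makes leading/trailing
*gene* characters free, so a transcript may cover a sub-region of a padded
gene region; the mRNA is always aligned end to end. Indel runs are
normalized to their leftmost score-equal placement (the usual VCF-style
left-shift, `canonicalize()`), which makes event positions deterministic;
counts are placement-invariant. Two invariants are asserted throughout:
length conservation (|mRNA| = |gene span| + n_ins - n_del) and the
reconstruction round trip (`apply_edit_events()` reproduces the mRNA exactly).

`oracle_align()` is a deliberately independent check: a memo-free recursive
enumeration of *all* admissible alignments for tiny inputs (gene ≤ 10,
mRNA ≤ 12). The acceptance suite compares the DP optimum against it on 200
random pairs.

## Editing statistics

`summarize_editing()` reports per-transcript insertion/deletion totals and
percent expansion, defined exactly as 100·(n_ins - n_del)/gene_len with the
*aligned gene span* as denominator (the transcript is compared with "the
corresponding gene sequence", not the whole contig). Pattern classification
(`classify_pattern()`) bins the gene into 20 equal bins, marks a bin edited at
≥ 1 site, and labels PAN (≥ 70% of bins edited), FIVE_PRIME (edited bins
confined to the first 25%), FIVE_AND_THREE_PRIME (confined to the first and
last 25%), else UNEDITED (always when < 3 sites). The class names come from
the biology; the numeric cutoffs are this package's decisions, exposed as
arguments, since no standard cutoffs exist for them.

Deaminative clusters (`detect_deaminative_clusters()`) are maximal chains of
substitution events with consecutive gaps ≤ 30 nt (the span observed for the
single reported 12S cluster) and ≥ 3 members, so one isolated tolerated
mismatch never forms a "cluster". `stop_created_by_editing()` translates the
mature mRNA under NCBI genetic code 4 by default (TGA = Trp, the
kinetoplastid mitochondrial code) and asks whether the first in-frame stop
overlaps an inserted U or a U-deletion junction.

## Minicircles and gRNAs

`find_grnas()` compares each minicircle strand with the reverse complement of
each edited mRNA, so Watson-Crick pairing becomes character identity and the
two legal wobbles become (gRNA G vs revcomp A) and (gRNA T vs revcomp C).
Candidate diagonals are seeded with exact 9-mers; each diagonal is scored per
pair (WC +1, wobble +0.5, mismatch -1) and the best contiguous segments are
extracted (repeated maximum-subarray with masking). A reported duplex must be
≥ 25 nt, contain a perfect-WC anchor run ≥ 6 nt, and have ≤ 10% mismatches;
wobble support can be switched off (`allow_wobble = FALSE`) to mimic plain
nucleotide-similarity searching. The 9-mer seeding assumes a duplex contains
at least one 9-long perfect WC run; at the simulated 5% wobble-conversion
rate the chance of violating this on an 85-nt cassette is negligible, and
`min_anchor` already demands a 6-run.

`find_backbone()` calls positions of a contig "backbone" when local hits at
≥ 90% identity from ≥ 2 other contigs cover them, merging runs ≥ 100 nt —
the shading rule used for minicircle backbone figures. `classify_contigs()`
labels a contig MAXICIRCLE_LIKE on cryptogene-scale depleted-space evidence
(≥ 100 depleted columns, which gRNA cassettes cannot reach: an 85-nt cassette
leaves ~45 depleted columns) or standard-space rRNA evidence, and
MINICIRCLE_LIKE on backbone sharing within a configured length range
(presets: 1300-2200 bp and ~600 bp). `detect_circularity()` reports the
longest duplicated terminus (prefix = suffix up to a mismatch budget), which
is evidence of circular-mapping, never proof — assembly can fabricate such
overlaps, and the classification output keeps it as a flag beside the label
rather than folding it into the label.

## Spliced leaders and motifs

`detect_sl()` matches *suffixes* of SL references (trans-splicing attaches
the SL 3' end) of length ≥ 10 within the first 40 nt of a transcript,
tolerating 1 mismatch by default — switchable to 0 for a strict "identical
sequences" criterion. Best match = longest, then fewest mismatches, then
TARGET over PREY; an exact TARGET/PREY tie is AMBIGUOUS rather than silently
assigned, because SL sequences of related taxa are near-identical. The
default reference is the full 17-nt prokinetoplastid SL-region string
TTACAGTTTCTGTACTT (sometimes loosely called a "10 bp" group-specific motif;
its conserved core is shorter than the printed string, and this package uses
the full string both as the simulator's planted SL and as the detector's
default reference).

`scan_motif()` matches a small degenerate pattern language — IUPAC literals
with mismatch budgets, length-ranged gaps, and paired stem halves with
optional G:U and a mispair budget — on both strands, resolving overlaps
leftmost-first per strand. It covers the 9S "530 loop" / 12S "A-loop"
stem-loop use case without implementing a full pattern grammar.
`compare_to_reference()` counts identical vs compensatory stem columns
against a reference pairing (compensatory = both structures pair, with
different pairs), the standard evidence for conserved secondary structure.

## Decontamination, mapping, polarity

`flag_prey_contigs()` applies the empirical contaminant rule — ≥ 93% identity
to a prey reference over ≥ 100 bp, both thresholds inclusive, identity =
matches / alignment columns including gaps (the rule's source does not define
identity; this matches the common convention of nucleotide search tools and
is tested at the exact boundary). `map_transcripts()` maps unspliced (no
split alignments — justified by the absence of cis-introns in these genomes)
at a 90% identity floor; `polarity_report()` orders mapped genes per contig
and reports strand runs, the majority-strand fraction and intergenic
distances, clipping overlaps to 0 with a flag so means stay interpretable.

## The simulator: what it emulates, and what it does not

`simulate_bundle()` draws, per preset:

* mt genes (uniform length 400-1200 nt, i.i.d. uniform composition with
  configurable GC) and their editing: per-gene insertion totals from a
  truncated normal matching the preset mean/range
  ("ankaliazontas": 389 [166-885] insertions, 29 [13-49] deletions,
  PAN-dominant; "spiralis": 166 [19-331], 43 [17-80], terminal-editing
  dominant), insertion run lengths geometric (p = 0.5, capped at 6),
  deletions of k ≤ run-length U's from gene T-runs. The pattern class
  controls *where* events fall (whole gene vs terminal 24% windows), not how
  many there are.
* placement constraints that make the planted event set the unique
  score-optimal canonical explanation: insertion points follow a non-T gene
  character (already leftmost), deletions sit at T-run starts, insertions
  keep ≥ 2 nt apart and clear of deletion runs, and the outer 5 nt of each
  gene stay edit-free so alignments anchor. These are conditions of the
  simulation chosen from how U-indel alignment ambiguity works; under them
  "recovered n_ins/n_del equals truth exactly" is a meaningful test rather
  than a coin flip over equivalent placements. When a drawn total exceeds a
  short gene's placement capacity, surplus U's are redistributed onto placed
  runs (up to the run cap) and the *realized* totals are the recorded truth.
* maxicircles: a shared 400-nt backbone plus 1-3 cryptogenes on random
  strands, optionally with a 120-nt duplicated terminus (circular-mapping);
  an rRNA-like gene carrying the deaminative cluster (8 C-to-U + 4 A-to-I
  within 30 nt) and a planted 6-bp-stem/GAAA-loop hairpin for motif-scan
  demonstrations.
* minicircles: shared-prefix backbone mutated at 2% per copy, carrying 1-2
  85-nt cassettes that are reverse complements of random edited-mRNA blocks
  with 5% of pairs converted to wobble.
* nuclear contigs: same-strand gene clusters, intergenic gaps geometric
  around 76 nt (or constant, `intergenic_mode = "fixed"` — the mode used when
  a test requires the spacing itself to be the condition); one transcript per
  gene, a Bernoulli(0.70 or 0.58) subset carrying the SL prefix; prey
  contigs and contaminant segments copied at an exact per-base identity.

Everything is a pure function of `sim_params()` (including the seed):
identical parameters give byte-identical outputs.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: realistic base composition and repeats (background is
i.i.d.), sequencing error and coverage (no read-level simulation), assembly
artifacts (chimeras, collapsed repeats), partially edited intermediates and
misediting, gRNA anchor/guiding-block structure beyond plain antisense
complementarity, and any phylogenetic signal. Recovery rates on this
synthetic data are upper bounds for real assemblies.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; 1-based values
  appear only in report columns suffixed `_1based` (none currently).
  RNA is stored as DNA (U as T); reports speak of "U" insertions/deletions.
* Ties in the DP are broken by a fixed state preference (match > deletion >
  insertion) and then removed entirely by left-shift canonicalization; hit
  lists sort by score, then subject id, then position, so all outputs are
  deterministic and `run_pipeline()` reruns are byte-identical (the manifest
  deliberately contains no timestamps).
* `write_table()` renders floats at 6 significant digits; computations are
  done on full precision and only rendering is rounded.
* Degenerate inputs: empty FASTA, duplicate ids, non-alphabet characters,
  empty stats tables, zero-length genes, unknown genetic codes and malformed
  motif patterns all fail with explicit errors; an alignment with no
  admissible path returns an `unalignable` result rather than throwing.
* Problem sizes in the tests and the acceptance script — 14 genes for
  end-to-end recovery, 50 cassettes, 1000 transcripts for the SL fraction,
  500 genes for the law-of-large-numbers check — were chosen as the smallest
  sizes at which the corresponding statistics are stable.

## Known limitations

* The editing aligner reports one optimal alignment; co-optimal *event sets*
  (as opposed to placements, which canonicalization resolves) are not
  enumerated. On heavily edited real transcripts with sequencing error the
  reported counts are a maximum-score point estimate.
* `tdepleted_search` identity is computed in depleted space and is not
  comparable with standard-space identity.
* `detect_circularity` compares exact termini; it will miss circular
  junctions hidden by indel errors.
* The motif language has no nested or pseudoknotted stems beyond what
  ordered open/close ids express, and no per-position scoring.
* The pipeline assumes one mature transcript per gene; alternative editing
  states of the same gene will each be aligned independently.
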
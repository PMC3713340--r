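---
title: "Tandem TGAC dyad elements: scanning, background statistics and induction analysis"
author: "beldyad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem TGAC dyad elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beldyad)
```

## The biological question

BEL1-like and KNOX (three-amino-loop-extension, TALE) homeodomain
transcription factors act as heterodimers — in potato, StBEL5 with its
Knotted1-like partner POTH1 — and bind a *tandem* arrangement of two short
TGAC-core motifs in the promoters of hormone-pathway target genes. A single
4–5 nt core is far too common in a genome to be informative; the functional
signal is the *dyad*: two cores, on either strand, separated by a short
linker. `beldyad` turns that definition into a reproducible pipeline:

1. extract strand-aware upstream windows from a genome (FASTA + GFF3),
2. find all maximal cores on both strands and pair them into dyads under a
   linker constraint, classifying each dyad's strand orientation,
3. quantify how surprising a dyad is in random sequence of matched
   composition (an exact dynamic program plus Monte-Carlo cross-check),
4. analyse qPCR induction data downstream of the motif analysis
   (comparative-threshold-cycle fold changes, replicate t-tests, and the
   linker-length/induction rank correlation).

A synthetic-data module generates every input the pipeline needs — core-free
promoter backgrounds with elements embedded at exact distances, synthetic
genome/GFF3 pairs, and simulated replicate Ct tables — so the whole analysis
is testable without downloads.

## The scanner definition

A **core** is a maximal occurrence of:

* `TGAC` on the plus strand, extended to `TTGAC` when the preceding base is
  T;
* `GTCA` on the plus-strand text (i.e. the core lies on the minus strand),
  extended to `GTCAA` when the following base is an A.

The published element strings mix the 4- and 5-mer forms (e.g. `TGACTTGAC`,
`GTCAtGTCAA`), which is why the scanner treats the 5-mer as the maximal form
of the same hit rather than a separate motif; longer extensions are not
considered. A useful structural fact, asserted as a property test, is that
maximal cores can never overlap: no suffix of any core word is a prefix of
another.

A **dyad** is an ordered pair of distinct cores whose linker — the
nucleotides strictly between the left core's end and the right core's start
— is between 0 and `max_linker` nt. The default cap is 24 nt, the longest
linker in the published element set; a zero-linker dyad (abutting cores) is
an ordinary dyad, not a special case. All qualifying pairs are reported by
default because real probes genuinely contain more than two cores (the IPT
gel-shift oligo has three cores and therefore three dyads with linkers 2, 8
and 14 nt); whether the original survey considered all pairs or only
consecutive cores is not stated, so all-pairs is the default and
`adjacent_only = TRUE` is available.

**Orientation** reads the two cores as arrows (5'→3' along the strand that
spells TGAC) from left to right: `(+,+) → TtH`, `(+,-) → TtT`,
`(-,+) → HtH`, `(-,-) → HtT`. All four classes occur among the published
elements, and reverse-complementing a window maps dyads onto each other with
HtH and TtT fixed and HtT ↔ TtH swapped — a symmetry the test suite fuzzes.

```{r}
els <- bel5_target_elements()
dyads <- scan_sequences(stats::setNames(els$element, els$gene))
dyads[, c("gene_id", "orientation", "linker_length")]
```

## Distance conventions and upstream extraction

Windows are reported 5'→3' in gene orientation, so the rightmost base is the
base immediately before the anchor. "Distance upstream" is the 1-based
position of the dyad's 5'-most base counted from the right end; the
annotation "element begins 820 nt upstream" is read as the element's *first*
base sitting at distance 820. A `distance_to = "3prime"` mode exists for
sensitivity analysis. Two anchors are supported, matching the mixed
annotations in the published tables: `TSS` (5' end of the gene feature) and
`AUG` (5' end of the CDS in gene orientation). Coordinates are GFF3-style
1-based inclusive throughout; the only conversion (to BED's 0-based
half-open) happens in the BED writer.

The default window is 2000 nt — the "within 2.0 kb of the start codon"
search criterion. For the AUX/IAA survey we use a 3000-nt preset instead,
because the published distances in that family run to 2524 bp while the
2-kb criterion is stated only for the first survey; the 3-kb figure is a
package choice, flagged here, not a published parameter. Ambiguity codes
(N) pass through extraction and never match a core.

## The synthetic-data generators

`generate_corefree_background()` draws i.i.d. bases at a requested GC
fraction and rejects — redrawing offending 4-windows — until neither `TGAC`
nor `GTCA` occurs. Forbidding those two words on the plus-strand text
forbids cores on *both* strands, because a minus-strand core appears on the
plus text as exactly one of those 4-mers. This guarantee is what makes the
embed-then-scan truth table exact: every dyad the scanner reports in a
synthetic window is a planned one.

`build_promoter_set()` splices elements in by *replacement*, preserving
window length so planned distances stay exact, and embeds the element string
verbatim (published cores upper-case, linkers lower-case; the scanner is
case-insensitive). Splice junctions can create incidental cores — or extend
a planned terminal core by an adjacent background T/A — so after splicing
each window is re-scanned and the background redrawn until the observed core
set equals the planned one exactly. `build_synthetic_genome()` wraps the
windows in one contig per gene (alternating strands by default, with the
whole contig reverse-complemented for minus-strand genes) plus gene/mRNA/CDS
features sharing one span, so TSS- and AUG-anchored extraction both recover
the generated windows; note that FASTA round-trips normalise case.

What the generator does *not* emulate: real promoters are not i.i.d.
sequence (no dinucleotide or Markov structure), elements are embedded free
of flanking context, and genes have no UTR separating TSS from AUG. Passing
the round-trip tests therefore demonstrates correctness of the coordinate
arithmetic and scanner, not performance on real genomes.

`simulate_ct_table()` inverts the comparative-threshold-cycle measurement
model: per replicate, target Ct = baseline − log2(expression) + Gaussian
noise (default sd 0.3 cycles, a typical replicate spread for SYBR assays;
default 3 replicates, matching the triplicate design of the published
assays), with the reference-gene Ct independent of condition. With zero
noise the downstream estimator recovers the true fold change exactly.

## The background model

For an i.i.d. window, `expected_core_sites()` is the linearity-of-expectation
count of 4-mer match positions on both strands, `2 (L−3) p_A p_C p_G p_T`
(both core words use each base once). Maximality is deliberately ignored in
this count — it is a site count, not a maximal-hit count.

`dyad_probability()` computes the exact probability that a window contains
at least one dyad under the scanner's definition, by dynamic programming
over positions. The state couples an Aho–Corasick-style automaton over the
two core words with the capped distance since the most recent core end
(distances beyond `max_linker + 6` cannot matter); completing a core with a
qualifying linker absorbs into an accepting state. Because cores never
overlap, the most recent core always yields the shortest candidate linker,
so one distance suffices.

Two refinements make the DP agree *exactly* with the scanner rather than
with a naive 4-mer approximation. Maximal extension changes dyad geometry:
a right core `TGAC` preceded by T is really `TTGAC`, whose start — and hence
its linker — is one base further left, and a left core `GTCA` followed by A
is really `GTCAA`, whose end is one base further right. (Concretely,
`TGAC` + 3 nt + `TTGAC` has a maximal linker of 3 but a 4-mer linker of 4,
so the two definitions disagree whenever such a dyad sits exactly at the
linker cap.) The DP therefore carries a preceding-base flag along the
T-G-A-C path and a one-step lookahead state after each completed `GTCA`.
The test suite pins the DP against an independent compiled brute force that
enumerates every sequence up to length 12 and re-scans it literally, across
linker caps and base compositions, and against seeded Monte-Carlo rates at
window lengths 50, 200 and 2000 (within three binomial standard errors).
Probabilities are propagated directly (total mass is conserved, so there is
no underflow concern at these window lengths).

```{r}
background_report(background_spec(window_length = 2000, max_linker = 24))
```

This is the number the motif survey needs for context: in 2 kb of random
50%-GC sequence a chance dyad is not rare, which is why the analysis leans
on exact element identity, orientation and linker statements rather than on
mere presence. The model is i.i.d. only; a Markov background is future
work.

## Induction analysis

`fold_change()` implements the comparative-threshold-cycle (Livak) method:
ΔCt = target − reference per replicate, ΔΔCt = mean ΔCt(treatment) − mean
ΔCt(control), fold change = 2^(−ΔΔCt). Significance is a two-sided
two-sample Student's t-test on per-replicate ΔCt values — the Ct scale is
where the Gaussian noise model lives, so testing linear fold changes would
be wrong; the equal-variance form is the default with Welch's available by
flag. Stars follow the 0.05/0.01/0.001 convention. With a single replicate
the fold change is computed but the p-value is reported missing rather than
guessed. No multiple-testing correction is applied by default (per-gene
stars are the published convention); an efficiency-corrected mode
((1+E)^(−ΔΔCt)) is available but not asserted against any published value,
since the published primer efficiencies (97–110%) were reported per assay
without raw Ct values. Dispersion in reports is labelled explicitly as a
standard deviation or standard error rather than relying on a figure-caption
convention.

`linker_induction_correlation()` is a Spearman rank correlation of fold
change against linker length. Only the rank pattern is testable: the
published result is a qualitative negative trend across four induced genes
with linkers 0, 1, 4 and 12 nt, with no printed coefficient, so the tests
assert the sign and perfect-rank cases, not a magnitude.

```{r}
ct <- simulate_ct_table(qpcr_sim_spec(
  genes = c("iaa_a", "iaa_b", "iaa_c", "iaa_d"),
  fold_change = c(8, 6, 4, 2), n_replicates = 3, ct_noise_sd = 0.3,
  seed = 7))
res <- fold_changes(ct)
res[, c("gene", "fold_change", "p_value", "stars")]
linker_induction_correlation(res, c(iaa_a = 0, iaa_b = 1, iaa_c = 4,
                                    iaa_d = 12))
```

## Numerical and design choices

* **Maximality at splice junctions and caps.** All tie-break-ish decisions
  reduce to the maximal-core rule; a dyad is identified by its pair of core
  starts and nested/overlapping dyads are never merged.
* **Degenerate inputs.** Windows shorter than 8 nt cannot contain a dyad and
  yield empty results, not errors; constant input to the correlation is
  undefined and reported missing; a gene absent from one condition is an
  error.
* **Sequence case** is never meaningful to the scanner; it is preserved by
  the generators for readability and normalised by FASTA round trips.
* **The ambiguous survey rows.** One published annotation ("double,
  palindromic motif", element count 2 with one printed string) is carried in
  the data but excluded from count assertions; one element's 20-nt linker
  was published without its sequence and is represented by N placeholders,
  which scan correctly because N never matches a core. Asterisk marks on
  some published motifs have no machine-readable meaning and are not
  modelled.
* **Problem sizes in the test suite** (package choices): exhaustive scanner
  equivalence to a naive reference for all sequences of length ≤ 8 plus
  1500 seeded random sequences up to length 60 at three linker caps;
  exhaustive DP validation to length 12; Monte-Carlo checks with 400–3000
  replicates; 300–400 seeded simulations for the qPCR coverage, bias and
  sign-recovery properties.

## Limitations

The package reproduces the *motif* analysis and the quantification
*machinery*. It does not predict binding affinity (the gel-shift evidence is
wet-lab), does not model transcript isoforms or UTR structure, uses an
i.i.d. background only, and makes no attempt to reproduce measured
fold-change magnitudes, which depend on raw Ct values that were never
published.
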
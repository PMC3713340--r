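# beldyad

Strand-aware discovery of tandem TGAC-core (BEL1/KNOX-type binding)
cis-elements in upstream regulatory sequences, with exact background
statistics and a downstream qPCR induction analysis.

## The problem

TALE-class homeodomain transcription factors — in potato, the phloem-mobile
StBEL5 with its Knotted1-like partner POTH1 — bind their hormone-pathway
target promoters not at a single short motif but at a *dyad*: two TGAC
cores, on either DNA strand, separated by a short linker. A lone 4–5 nt
core is ubiquitous by chance; the informative signal is the pair, its
strand orientation, its linker length and its distance upstream of the
gene. `beldyad` is for regulatory genomicists who want that search to be
reproducible: a scanner with an explicit, tested definition, generators for
ground-truthed synthetic inputs, an exact null model, and the
comparative-threshold-cycle machinery used to score induction of the target
genes.

## The model

A **core** is a maximal occurrence of `TGAC` (plus strand; extended to
`TTGAC` when preceded by T) or `GTCA` (minus-strand core; extended to
`GTCAA` when followed by A), matched case-insensitively, never across
ambiguity codes. A **dyad element** is an ordered pair of cores with linker
length

    linker = right.start − left.end − 1   (0 ≤ linker ≤ max_linker, default 24 nt)

and orientation read arrow-wise left to right: `(+,+)→TtH`, `(+,−)→TtT`,
`(−,+)→HtH`, `(−,−)→HtT`. Distances upstream are 1-based positions of the
dyad's 5'-most base counted from the anchor (TSS or start codon). The
background model gives the exact probability that an i.i.d. window of given
length and base composition contains at least one dyad, via a dynamic
program over a core-word automaton coupled to the capped distance since the
last core end (validated against exhaustive enumeration in compiled code).
Induction is quantified as 2^(−ΔΔCt) with a Student's t-test on
per-replicate ΔCt and a Spearman rank correlation of fold change against
linker length.

## Worked example

Scan the packaged, published target-gene elements and probe oligos:

```r
library(beldyad)

els <- bel5_target_elements()
d <- scan_sequences(stats::setNames(els$element, els$gene))
d[d$gene_id == "StBEL5", c("orientation", "linker_length")]
#>   orientation linker_length
#> 1         HtH             3
range(d$linker_length[d$linker_length > 0])
#> [1]  2 24

oligos <- gelshift_oligos()
ipts <- pair_cores(find_cores(oligos$sequence[oligos$name == "IPTS"]))
sort(ipts$linker_length)
#> [1]  2  8 14
```

The StBEL5 autoregulatory element is a head-to-head dyad with a 3-nt
linker; across the target set, nonzero linkers span 2–24 nt; the IPT
gel-shift probe carries three cores, hence three dyads (all-pairs
reporting), the tightest with a 2-nt linker.

End-to-end on synthetic data — embed the element 820 nt upstream, build a
genome + GFF3, extract, scan, and ask how surprising the hit is:

```r
sg <- build_synthetic_genome(
  embed_plan("StBEL5", "GTCAAtgcTTGAC", 820, "TSS"),
  window_length = 2000, seed = 1)
write_synthetic_genome(sg, "toy.fa", "toy.gff3")
reg <- extract_upstream(load_genome("toy.fa"), read_gene_models("toy.gff3"),
                        anchor = "TSS", window_length = 2000)
scan_sequences(reg)[, c("gene_id", "orientation", "linker_length",
                        "distance_upstream")]
#>   gene_id orientation linker_length distance_upstream
#> 1  StBEL5         HtH             3               820

background_report(background_spec(window_length = 2000))[,
  c("expected_core_sites", "dyad_probability")]
#>   expected_core_sites dyad_probability
#> 1            15.60156        0.9137943
```

In 2 kb of random 50%-GC sequence a chance dyad (linker cap 24 nt) is
likely, which is why the analysis rests on element identity, orientation
and linker statements rather than mere presence.

Simulated qPCR induction with the published linker spacing:

```r
ct <- simulate_ct_table(qpcr_sim_spec(
  c("iaa_a", "iaa_b", "iaa_c", "iaa_d"), fold_change = c(8, 6, 4, 2),
  n_replicates = 3, ct_noise_sd = 0.3, seed = 7))
linker_induction_correlation(fold_changes(ct),
                             c(iaa_a = 0, iaa_b = 1, iaa_c = 4, iaa_d = 12))
#> $rho
#> [1] -0.8
```

(Replicate noise at sd 0.3 cycles occasionally swaps adjacent ranks — here
two mid-ranked genes — but the negative trend is recovered; the test suite
shows the sign is recovered in over 99% of seeded simulations.)

A command-line front-end is available at `exec/beldyad`
(`beldyad scan | background | induce`).

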
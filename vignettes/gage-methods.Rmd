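---
title: "Methods: CRISPR/Cas12a target design for species identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR/Cas12a target design for species identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gage)
```

## The model

A Cas12a *target* is a 25-bp genomic window made of a 4-nt
protospacer-adjacent motif (PAM) and a 21-nt protospacer. LbCas12a requires
`TTTV` (V = A/C/G) immediately 5' of the protospacer, so on the forward
strand a usable window either *starts* with `TTTV` or — when the protospacer
sits on the reverse strand — *ends* with the reverse motif. Species
identification then reduces to finding a window that (i) exists in the
subject genome, ideally in many copies so that little input DNA suffices,
and (ii) has no relative within the off-target reach of Cas12a (three
protospacer mismatches) in any genome the assay must discriminate against.

The pipeline is deliberately exhaustive rather than heuristic: every window
of every sequence is enumerated, and the mismatch search is exact. There is
no scoring model — a site either satisfies PAM + distance or it does not —
which matches how off-target enumeration tools used for assay design work,
and makes every stage checkable against a brute-force oracle.

## Scanning semantics and their edge cases

`scan_targets()` slides a width-`k` window along the forward strand of each
sequence (`len − k + 1` windows per sequence; windows never span sequence
boundaries, because contigs are independent). Decisions worth stating
explicitly:

* **Ambiguity letters.** Windows containing any non-ACGT letter are skipped
  entirely — a probe cannot be synthesised against an ambiguous base. The
  letters still count toward genome length, since assembly length is the
  natural denominator for density. Soft-masked (lowercase) input is
  uppercased and treated as ordinary sequence.
* **Orientation.** A window matching both the forward-start and reverse-end
  motifs is counted once, with orientation `both`; for PAM/protospacer
  decomposition and crRNA design it reads as forward. A window is one
  occurrence regardless of how many motifs it satisfies, but in the
  *off-target* search a position can yield two hits, one per strand, if both
  strands independently satisfy PAM + distance.
* **Deduplication.** Identical k-mer strings aggregate into one record with
  a copy number; no canonicalisation across strands is applied, matching
  plain k-mer-counter semantics. The scanner aggregates into a keyed table
  without materialising non-PAM windows.
* **Reverse motif.** The default (`pam_pattern(mode = "paper")`) takes the
  reverse-oriented motif literally as `VAAA`. The biochemically symmetric
  choice is the reverse complement of `TTTV`, which is `BAAA`; that is
  available as `mode = "strict"`. The two differ on windows ending `TAAA`
  (strict-only) versus `AAAA`-adjacent `V` endings; both modes are first-class
  and every downstream step honours the library's mode. Strand-mirror
  properties (scanning a reverse-complemented genome) hold exactly in strict
  mode and are tested there.
* **Density.** Reported as genome length / *total* (non-deduplicated) target
  count — "one target per x bp". Using totals keeps the statistic
  scale-invariant (a duplicated genome has the same density) and anchors the
  percentage column of the classification table.

Degenerate inputs: an empty library makes density undefined (`NA` with a
warning rather than an error, so summaries over many genomes do not abort);
sequences shorter than `k` are rejected; `k` must exceed the PAM length.

## Annotation classification

An occurrence belongs to an annotation class when its **full window is
contained** in a feature of that class. Containment rather than overlap is
the right reading of "located in": a window straddling a CDS boundary cannot
serve as a CDS-specific probe. Classes are not forced to be mutually
exclusive — a window can be in a gene and in its CDS — except for the
annotated/unannotated split, which is computed against the *union* of coding
gene and ncRNA intervals so that `annotated + unannotated = genome` holds as
an identity even with overlapping features. "Coding gene" uses the gene-body
extent (genes with a protein-coding biotype or CDS descendants); per-gene
CDS coverage asks whether at least one window is contained in at least one
of the gene's CDS intervals, with base-level CDS coverage reported as a
secondary statistic.

## Off-target search and the specificity verdict

`find_offtargets()` reports every site whose PAM matches its IUPAC pattern
exactly (zero tolerance) and whose protospacer is within `max_mm` Hamming
mismatches of the query (mismatches counted on the protospacer only). Both
strands are scanned; hits are reported in forward-strand coordinates and
sorted `(seqid, start0, strand)`, so output order is total and reproducible.
The implementation prefilters PAM-valid positions with vectorised IUPAC
matching and computes Hamming distances only there; its contract is exact
equality with a brute-force double-strand scan, which the test suite
enforces on randomised instances.

The specificity verdict is asymmetric on purpose: a candidate **passes**
when every adulterant genome has zero sites within `max_mm` (default 3, the
conventional off-target reach), while presence in the subject genome is
reported but not enforced — the caller already knows the candidate came from
the subject's library, and may separately require a minimum copy number.
`select_final_targets()` ranks passing candidates by copy number descending
(high copy number means more template per nanogram of input DNA, hence
better sensitivity) with lexicographic k-mer order as the deterministic tie
break, and retains rejected candidates with the names of the genomes that
disqualified them.

## crRNA assembly

The crRNA is direct repeat (5') + spacer (3'), where the spacer is the
protospacer transcribed (T→U). The default repeat is the 21-nt mature
LbCas12a direct repeat `UAAUUUCUACUAAGUGUAGAU`; vendors ship slightly longer
precursor variants, so the repeat is a plain argument recorded in the output
rather than a hidden constant. Spacer length is `k − 4` (21 nt by default)
and follows `k` for other systems. No secondary-structure screening is
attempted.

## Detection calls and the limit of detection

Replicate fluorescence readings are compared group-versus-control at a
single caller-chosen timepoint (default 25 min, where the Cas12a reporter
signal typically plateaus) with a two-sample t-test. Welch's unequal-variance
form is the default since nothing guarantees equal variances across a
dilution ladder; the pooled form is available. The call is one-sided in the
only meaningful direction, implemented as a two-sided p-value plus a
mean-above-control guard; `detected` requires p < alpha (default 0.01) *and*
a higher group mean. Testing one timepoint avoids per-timepoint multiplicity
correction, which single-threshold assay calls do not employ; the timepoint
is a parameter, not a discovery procedure. With constant readings in both
groups the t-statistic is undefined; the call degenerates to p = 1 when the
means agree and p = 0 otherwise.

`lod_scan()` orders groups by concentration, calls each against the control,
and reports the smallest detected concentration, plus a monotonicity flag
that warns when an undetected concentration lies above a detected one.

## What the synthetic data emulates — and what it does not

The generators exist so that every stage has a fixture with *exact* ground
truth:

* `generate_genome()` draws i.i.d. background from configurable base
  frequencies (`at_rich_freqs()`, 33% A/T, approximates plant-genome PAM
  density; uniform frequencies give the analytic density
  `1/(2p − p²)` with `p = (1/4)³ · (3/4)` ≈ 42.9 bp per target, used as a
  closed-form check on a 1-Mb genome). Planted sites are spliced in at
  non-overlapping positions with Hamming edits confined to the protospacer.
  After generation the genome is *verified*: a full mismatch search for each
  planted (and each explicitly avoided) protospacer must recover exactly the
  planned occurrences, otherwise the genome is regenerated from a derived
  seed. Truth tables are therefore exact, not probabilistic, and oracle
  tests can assert equality instead of tolerances.
* `generate_adulterant()` applies i.i.d. substitutions at a given rate. At
  25% divergence a 21-nt protospacer expects ~5.25 mismatches, safely beyond
  the 3-mismatch radius for most sites — emulating the contrast between a
  subject genome and a different species.
* `generate_assay_series()` produces
  `baseline + A(c)·(1 − e^{−t/τ}) + N(0, σ)` with a Hill-type amplitude
  `A(c) = A_max / (1 + (K/c)^h)`. Defaults (A_max = 2000, baseline = 100,
  σ = 50 fluorescence units, τ = 8 min, h = 4, K = geometric mean of 0.01
  and 0.001 ng/µL) put the planted threshold at 0.01 ng/µL on the standard
  ten-fold ladder: concentrations a step above the midpoint saturate near
  the plateau, a step below sit under one noise SD. The steep transfer
  models the threshold-like response of amplification-free Cas12a reporter
  assays, whose usable dynamic range between noise floor and plateau is
  narrow.

What the generators deliberately do **not** model: indels and rearrangements
(divergence is substitution-only, so the off-target search never faces
bulges — which the search itself also does not model), phylogenetically
realistic divergence, repeat structure and GC heterogeneity of real plant
genomes, sequencing or assembly error, and kinetic saturation differences
between replicates. Passing tests therefore demonstrate algorithmic
correctness on the stated model, not performance claims about any real
assembly.

## Problem sizes and seeds

All randomness flows through explicit integer seeds (scoped, never touching
the caller's RNG state). The test suite runs the scanner against its regex
oracle on 200 random genomes up to 5 kb, the off-target search against brute
force on 100 instances up to 20 kb, the closed-form density check on 1 Mb,
the planted-truth selection fixture on a 50-kb subject with three 20-kb
adulterants, and limit-of-detection recovery over 200 simulated ladders
(requiring ≥95% recovery of the planted threshold; the t-test's ~0.5%
one-directional false-positive rate at alpha 0.01 makes occasional misses
expected). These sizes keep the whole suite within a couple of minutes while
leaving each property statistically sharp.

## Known limitations

* No bulge (indel) off-target modelling and no cleavage-efficiency scoring;
  the mismatch count is the only specificity currency.
* The classification table reflects the supplied annotation's feature types;
  unannotated simply means "not contained in a coding-gene or ncRNA
  interval".
* Whole-genome scanning is in-memory and single-threaded; multi-Gb
  assemblies are better handled per sequence or via region-restricted
  libraries (`build_region_library()`), which is also the practical route
  for barcode regions.
* Detection calls test one timepoint; callers wanting curve-level inference
  should fit kinetics upstream and feed derived endpoints in.
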
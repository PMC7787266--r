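---
title: "Methods: resolving telomere fusion junctions through crisis"
author: "telocrisis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resolving telomere fusion junctions through crisis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telocrisis)
```

## The problem

When human cells bypass senescence and continue dividing, telomeres erode
until they lose end protection and the cell enters replicative crisis:
deprotected chromosome ends are handled as double-strand breaks and fuse —
to their own sister chromatid (intra-chromosomal), to another telomere
(inter-chromosomal), or to an internal genomic locus (genomic fusion).
Fusion amplicon sequencing targets a small set of chromosome ends whose
subtelomeres are unique enough to carry a single-molecule PCR primer (17p,
XpYp, and the homologous 21q family), amplifies fusion products, and
sequences them. The analysis questions this package addresses are:

* resolve each amplicon to a base-resolution junction: where on the
  subtelomere did the break occur, what is the partner locus, how much
  microhomology (MH) does the junction use, does it carry an inserted
  segment (INS) and was that insertion copied (templated) from sequence
  near the break;
* quantify subtelomeric deletion and the asymmetry (delta deletion)
  between the two chromatids of an intra-chromosomal fusion;
* ask where fusions land in the genome — per-chromosome rates against
  size-predicted expectations, coincidence with genes, exons, promoters,
  enhancers, fragile sites and LTR repeats — always against a null of
  simulated fusions ("simulants") resolved by the identical methodology;
* call gross copy-number alterations (CNA) from single 4N-nucleus
  sequencing binned against a pooled-nuclei baseline and intersect them
  with fusion loci;
* link fused genes to stage-labelled expression (Early, Deep, Late
  crisis).

Every layer has a synthetic counterpart with recorded ground truth, so the
whole pipeline is testable end to end.

## Junction resolution

A fusion read is split-aligned: the prefix anchors in a targeted
subtelomere (plus strand, downstream of the primer), the suffix at the
partner locus on either strand, via exact 21-mer seeds and ungapped
extension. Junction metrics then come from a closed form. Let `a` be the
maximal exact extension of the read along the subtelomere and `s` the
maximal exact backward extension along the partner, with read length `n`.
Every perfect split placement of the read lies at a split position in
`[n - s, a]`, so:

* if `a + s >= n`, the junction has `mh = a + s - n` (the width of the
  placement window; MH makes the exact breakpoint ambiguous and is the
  signature of alternative end-joining);
* otherwise no perfect placement exists, `mh = 0`, and the middle segment
  `read[(a+1)..(n-s)]` is the insertion.

Breakpoints are reported at the **leftmost** valid placement, 0-based
half-open, with `mh_bp` giving the ambiguity width. A test-suite invariant
holds this closed form against a brute-force enumeration over every split
position. Insertions are classified *templated* when the inserted sequence
(or, by default, its reverse complement — synthesis during end-joining is
not strand-constrained, and the flag is configurable) occurs verbatim
within +/-100 bp of either breakpoint flank.

Intra- and inter-chromosomal events are read from either fused end
depending on read orientation, and the leftmost-placement convention is
side-dependent: the mirror reading reports the opposite edge of the MH
window. Calls are therefore put into a canonical orientation
(lexicographically smaller end/breakpoint as the A side) with both
coordinates shifted by `mh_bp` on a swap, which makes the two readings of
one junction collapse in deduplication. A read whose partner segment
scores equally at two unrelated loci is flagged unclassifiable and
excluded (the mirror reading of the same junction is recognised and is
not ambiguity); 21q-family ties resolve to the archetype, and intra status
on the 21q family additionally requires the mapped window's identity to
the archetype to beat every sibling by a 2% margin (default), otherwise
the conservative inter assignment is made.

Deletion is measured back from the telomere-repeat boundary:
`deletion = telomere_boundary - breakpoint`; for an intra event the
asymmetry is `delta = |d1 - d2|`. Calls agreeing in category, ends and
both breakpoints within 5 bp merge, summing supporting reads; junction
metrics come from the most-supported variant. Mate pairs that straddle a
junction without a junction-spanning read yield interval-resolution calls,
which are excluded from MH/INS summaries.

## The synthetic data layers

`sim_config()` fixes the study conditions; `build_reference()` generates a
minigenome (default 4 x 500 kb) plus subtelomere references for 17p, XpYp,
the 21q archetype and a diverged, non-targeted 21q sibling (8% per-base
divergence) that reproduces the family cross-mapping problem. Annotation
tracks are laid down at per-kb densities; gene lengths are log-normal so
that a long-gene tail exists (the genome-scale quantities are scaled down
~100x relative to a human genome, e.g. mean gene length ~0.5 kb).

`simulate_fusions()` draws classes from `class_mix` (default 0.4 genomic /
0.4 intra / 0.2 inter), subtelomere breakpoints through the deletion law
(`deletion ~ U(deletion_range)`), microhomology from a geometric law of
mean `mh_mean = 2` truncated at `mh_max = 12`, and insertions with
probability 0.3, lengths 1–15 bp, templated with probability 0.5.
Insertions force MH to 0: under exact matching a junction cannot carry
both an unexplained insertion and placement ambiguity, and keeping them
exclusive keeps the truth unambiguous for recovery tests.

Microhomology of length k is *injected* by overwriting the k
junction-proximal partner bases in the reference to match the subtelomere
side, and setting one blocking base beyond each edge of the window so the
realised placement window is exactly k wide. Because the reference is
edited, `simulate_fusions()` returns the patched reference with the truth
table, and rendering/calling must use it. Read/write masks guarantee no
patch lands on a base another junction's structure depends on; the class
and junction structure of an event are drawn once and only coordinates are
redrawn on conflict, so placement rejection cannot bias the class mix or
the MH law. Under extreme congestion (far more junctions than the fusion
zones can hold) the requested MH degrades one base at a time until the
event places — the truth records what was actually placed. After
placement, every junction is re-resolved against the final reference and
the run aborts on any mismatch; templating flags are likewise re-verified
against the final sequence.

Simulants (`generate_simulants()`) draw breakpoints uniformly between
primer and telomere boundary and partner coordinates uniformly over the
genome, with MH 0 and no insertion enforced by rejection only — the
reference is never edited — and their reads go through the identical
rendering and calling path. Biological breakpoints are also uniform over
the deletion range by default (`ltr_avoid = 0`): the subtelomeric LTR
depletion seen in real data has no stated generating mechanism, so the
generator does not build one in; depletion demonstrations construct
avoidance explicitly.

Reads are 250 bp paired ends off ~Normal(450, 40) fragments (overlapping
mates, as in amplicon sequencing), with uniform fragment placement and
per-base substitution errors (`error_rate`, default 0). `coverage` is a
fragment depth: an amplicon of length L yields
`round(coverage * L / frag_mean)` pairs, which makes the expected
sequenced bases `coverage * L * 2 * read_len / frag_mean` and gives every
junction a high probability of junction-spanning coverage at the default
coverage 10.

The 4N-nucleus layer tiles the minigenome into equal bins (2,000 by
default) and draws per-bin counts Poisson around `depth x copy_ratio`,
ratio 1 for neutral bins, 5/4 for a single-chromatid gain and 3/4 for a
loss on the 4N background; the bulk baseline aggregates 500 neutral
nuclei. The expression layer draws negative-binomial counts (size 200,
i.e. low-dispersion replicate cultures) around log-normal base means
(~100) with programmed per-stage folds and library sizes varied uniformly
in [0.5, 2].

What the synthetic layers do **not** emulate: PCR chemistry (chimeras,
slippage), indel sequencing errors, GC- or mappability-biased coverage,
satellite/repeat structure beyond the planted LTR-like intervals and 21q
homology, amplification noise of single-nucleus whole-genome
amplification, and biological dispersion between donors. Passing tests
therefore demonstrate that the algorithms are correct on data satisfying
their stated models, not that the defaults are tuned for any particular
real library.

## Enrichment statistics

A junction is a point (the leftmost breakpoint); feature membership is
point containment. Per-chromosome expectations multiply the overall
events-per-kb frequency by chromosome size (`e_i = total * L_i / sum L`,
so expectations sum exactly to the observed total) and each chromosome is
tested with a two-cell goodness-of-fit chi-squared. Feature coincidence
forms a 2x2 table of junctions in/out of a track against either the
genome fraction the track covers or a matched simulant set; the
chi-squared (no continuity correction) is used when all expected cells are
at least 5, otherwise Fisher's exact test, and a `method` argument can
force either route. `fisher_exact_2x2()` enumerates hypergeometric
weights as exact integers (`choose(r1, x) * choose(r2, c1 - x)` stays
below 2^53 for every table this package meets) and sums those at most as
probable as the observed table; a zero margin gives p = 1. Multiple
units are reported without multiplicity correction, mirroring per-unit
reporting; `stats::p.adjust` can be applied downstream. Comparisons of
mean gene lengths use the normal summary-statistics z test
(`compare_means()`).

## Copy-number calling

Per-nucleus bin counts are normalised as
`r_i = log2((c_i / C) / (b_i / B))` against the pooled baseline (bins with
zero bulk counts are masked). Segmentation is a deliberately simple,
deterministic rolling median (window 5 bins) followed by thresholding at
+/-0.25 — between 0 and the single-chromatid 4N changes log2(5/4) = 0.32
and log2(3/4) = -0.415 — with same-call runs bridged across up to one
neutral bin and runs shorter than 5 bins dropped. At depth 500 the
per-bin noise SD is ~0.06, so a five-bin median crossing 0.25 by chance
is vanishingly rare while a true single-chromatid change clears the
threshold with margin; this trades sophistication for testability and
exact boundary behaviour (an injected segment's boundary is recovered
within one bin). GC correction is omitted (the synthetic genome is
GC-neutral) and would be required on real data. Fusion-CNA intersection
uses the same Fisher machinery as the enrichment module, with matched
simulant junctions as the control set.

## Expression linkage

Size factors are median-of-ratios: the reference is the per-gene
geometric mean over samples (genes with any zero excluded), the factor is
the median ratio to that reference, and normalised counts are counts over
factor — the proportional two-sample case has the closed form
(1/sqrt(2), sqrt(2)). Expression status is three-way on stage-mean
normalised counts: >= 5 expressed, < 1 not expressed, in between
ambiguous (the thresholds are declared defaults, not inferred from any
dataset). Fused genes are linked stage-matched: fusions from stage s
against expression at stage s, reporting the fraction expressed and the
fold of mean normalised counts over all genes. "Top differentially
expressed" lists rank |log2 FC| between two stages after a minimum-mean
filter with a pseudocount of 1; no dispersion-model inference is
attempted — fold-change ranking on normalised counts is the declared
stand-in, and the full negative-binomial machinery of dedicated
differential-expression packages is deliberately out of scope.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and in BED output; TSV
  round-trips are exact.
* All randomness derives from one master seed through stable string-tagged
  sub-seeding (`derive_seed()`), so each layer is reproducible
  independently of how many draws the others consume.
* Empty call sets, all-zero histograms, zero-margin tables, single-gene
  fused sets and missing stages all return defined values or named
  errors; `min_len = Inf` disables CNA calling; an all-zero nucleus is an
  error.
* The MH law is truncated at 12 bp so exact-MH flank windows stay small;
  the truncation is part of the declared law (its closed-form mean is
  used by the tests, e.g. 1.990 for `mh_mean = 2`).
* The seed-and-extend aligner requires the exact extension on each side
  to reach through its anchor seed; this prevents reads that barely
  overhang a junction from being reinterpreted as spurious fold-back
  junctions.

## Problem sizes

The test-suite and acceptance-script sizes are the package's declared
study scale: 2,000-event recovery cohorts at coverage 10 on the 2 Mb
minigenome; 1,000-junction oracle sweeps; 1,000-event asymmetry cohorts
per stage at coverage 8; 200 null-calibration replicates of 400 events
against 10,000 simulants; 23 nuclei x 2,000 bins at depth 500 over 20
specificity replicates; 2,000 genes x 9 samples expression matrices. The
demo pipeline (`run_pipeline()`) uses 300 events so an end-to-end run
completes in well under five minutes.

## Known limitations

* The caller is ungapped: junctions whose flanks carry indels relative to
  the reference are out of scope, as is quality-aware error handling.
* With sequencing errors enabled, junction metrics for a read with a
  substitution near the junction are resolved from the erroneous sequence;
  deduplication usually rescues the event via clean reads, but a
  `min_support` filter is the only chimera/error guard provided.
* Interval-resolution (mate-pair-only) calls locate an event only to a
  reference pair, not to coordinates.
* The family-identity rule assumes family members are positionally
  homologous (aligned coordinates), which the synthetic reference
  guarantees; diverged real families may need an alignment step first.
* The amplicon model for single-primer genomic fusions (partner segment of
  500–3,000 bp) is a declared convention for how such amplicons
  terminate, chosen to make read generation well-defined.
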
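# telocrisis

Analysis of telomere fusion amplicon sequencing through replicative
crisis, with matched synthetic data carrying recorded ground truth.

When telomeres erode past the point of end protection, chromosome ends are
repaired as double-strand breaks and fuse — to the sister chromatid
(intra-chromosomal), to another telomere (inter-chromosomal) or to an
internal genomic locus (genomic fusion). Fusion amplicon sequencing
amplifies these junctions from primers in the 17p, XpYp and 21q-family
subtelomeres. `telocrisis` resolves the reads into classified junction
calls and carries the downstream analyses:

* **Junction calling** — a seed-and-extend split aligner plus a
  closed-form junction resolver: with `a` the maximal exact extension of a
  read along the subtelomere and `s` along the partner (read length `n`),
  all perfect split placements lie in `[n - s, a]`, so microhomology is
  `mh = a + s − n` when `a + s ≥ n`, otherwise the unexplained middle is
  the insertion and `mh = 0`. Breakpoints are reported at the leftmost
  placement (0-based half-open). Insertions are *templated* when found
  within ±100 bp of either breakpoint flank. Subtelomeric deletion is
  `telomere_boundary − breakpoint`; intra-chromosomal events carry the
  asymmetry `Δ = |d1 − d2|`. 21q-family partners are assigned intra status
  only when identity to the family archetype beats every sibling by a
  margin (default 2%).
* **Simulant null** — bioinformatically simulated fusions with uniform
  breakpoints and clean junctions, rendered and called by the identical
  code path, form the null for every enrichment statistic.
* **Enrichment** — per-chromosome counts against size-predicted
  expectations (`e_i = total · L_i / ΣL`, two-cell χ²), junction–feature
  coincidence (2×2 χ², or exact Fisher when expected cells are small),
  fused-gene length statistics with summary z tests, and subtelomere /
  genome LTR coincidence against simulants.
* **Single-nucleus CNA** — per-bin `log2((c_i/C)/(b_i/B))` against a
  pooled-nuclei baseline, rolling-median segmentation with ±0.25
  thresholds (between 0 and the 4N single-chromatid changes log2(5/4) and
  log2(3/4)), and Fisher-tested intersection of fusion junctions with
  gain/loss segments.
* **Expression linkage** — median-of-ratios size factors, three-way
  expression status, stage-matched fused-gene expression folds, |log2 FC|
  top lists and cross-line overlaps.

The synthetic-data module generates all three data layers (fusion
amplicon reads, 4N-nucleus bin counts, stage-labelled count matrices) on a
scaled-down minigenome with exact truth records, including exact-MH
injection verified against the final reference.

## Worked example

```r
library(telocrisis)

cfg <- pipeline_config(seed = 7, out_dir = "demo_out",
                       n_fusions = 150L, n_simulants = 1500L,
                       n_nuclei = 6L, n_bins = 800L)
summary <- run_pipeline(cfg, quiet = TRUE)
str(summary)
#> $ n_truth              : int 150
#> $ n_reads              : int 45696
#> $ n_events             : int 151
#> $ recovery_pct         : num 100
#> $ mean_mh              : num 1.15
#> $ class_proportions    : genomic 0.417, inter 0.192, intra 0.391
#> $ gene_coincidence_prop: num 0.381
#> $ gene_fraction        : num 0.481
#> $ fused_gene_mean_len  : num 1054
#> $ fused_gene_vs_all_z  : num 3.58
#> $ n_cna_segments       : int 6
#> $ cna_fusion_overlap   : int 17
#> $ cna_fusion_p         : num 0.0316
#> $ size_factor_range    : num [1:2] 0.47 1.64
```

Reading the output: all 150 simulated fusions were recovered from the
reads (one event is reported twice at distinct coordinate pairs, hence
151); the recovered class proportions match the programmed 0.4/0.4/0.2
mix; mean junction MH reflects the geometric law thinned by
insertion-carrying junctions (which have MH 0 by construction); 38% of
genomic junctions fall in genes on a genome that is 48% genic; the six
planted CNA segments are found, and 17 fusion junctions intersect them
(Fisher p = 0.032 against the simulant control). `demo_out/` holds the
calls (TSV and BED), enrichment tables, CNA segments, normalised counts,
the resolved configuration and this summary as JSON.

A thin command-line wrapper is installed as `exec/telocrisis`
(subcommands `simulate`, `call`, `enrich`, `cna`, `expr`, `run`).

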
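# rddmtarget

Analysis of zinc-finger (ZF) **targeted RNA-directed DNA methylation
(RdDM)** experiments, with a fully seeded synthetic-data generator for
calibration and recovery testing.

Fusing RdDM components to an artificial zinc finger tethers the silencing
machinery to chromatin. The ZF's promiscuous off-target binding creates a
natural site universe to ask, locus by locus: is the fusion bound, is
Pol V recruited, are 24-nt siRNAs produced de novo, does DNA methylation
accumulate (CG/CHG/CHH), is it heritable after the transgene segregates
away, and does promoter-proximal methylation repress the neighbouring
gene? `rddmtarget` implements that chain end to end:

- **Methylation core** — per-cytosine levels *m = #C/(#C+#T)*, strand-aware
  context assignment (CG/CHG/CHH), removal of bisulfite-conversion-failure
  reads (> 3 consecutive methylated CHH calls), coverage gating (≥ 20 reads
  for amplicon data), coverage-weighted region summaries.
- **Anchored DMR calling** — 100-bp windows over 1-kb site flanks; pooled
  counts per group tested with a two-sided conditional exact test;
  hyperDMRs at difference ≥ 0.4/0.2/0.1 (CG/CHG/CHH) and q < 0.01; merge
  when gaps < 200 bp; cross-context combination; pre-existing-CHH and tRNA
  filters.
- **Shared count statistics** — median-of-ratios normalisation, exact-test
  p-values on pooled counts vs library remainder (for feature counts
  `k_A`, `k_B` with library totals `N_A`, `N_B`, the 2×2 table
  `[k_A, N_A−k_A; k_B, N_B−k_B]`), log2 fold changes with pseudocount,
  Benjamini–Hochberg FDR.
- **Site classification** — peak retention (> 2-fold), the inverted Pol V
  rule (*not* recruited iff fusion/Pol V > 4-fold at q < 0.05), siRNA
  production (≥ 1 bin with fold > 4, q < 0.05), the multilevel funnel,
  Venn partitions, metaplots, motif scanning.
- **Heritability** — decile ranking of regions by methylation difference;
  heritable iff segregant − control CG gain ≥ 0.10.
- **Expression integration** — RPKM, differential calls (fold > 2,
  q < 0.05), signed TSS distances, nearest-gene linkage, permutation-based
  observed/expected TSS-distance enrichment, flowering-time classification
  (early ≤ 20 leaves).
- **Synthetic data** — a seeded generator planting all of the above with
  known nested truth (hypermethylated ⇒ siRNA-producing ⇒ Pol V-recruited
  ⇒ bound), negative-binomial counts, binomial bisulfite data with
  conversion failures, and TSS-proximal repression.

Everything is data-frame-first: functions take tibbles, return tibbles,
chain with the pipe, and fitted result objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

```r
library(rddmtarget)

cfg <- sim_config(seed = 7, n_chromosomes = 2, chromosome_length = 120000,
                  n_sites = 50, n_genes = 40)
report <- run_pipeline(cfg)
print(report)
```

```
Targeted-methylation pipeline report
  seed 7, config hash 8ad37cba418200b319ae4be7ecf13ca0
  sites: 50 | hyperDMRs: 4 | motif fraction: 1.00
  funnel:
    1. bound            n =   50 (100.0% of previous)
    2. polv_recruited   n =   45 (90.0% of previous)
    3. sirna_producing  n =    9 (20.0% of previous)
    4. hyperdmr         n =    4 (44.4% of previous)
    5. repressed_gene   n =    3 (75.0% of previous)
```

The funnel narrows exactly as the generator planted it: all 50 motif sites
are bound, 45 recruit Pol V, 9 produce 24-nt siRNAs, 4 gain methylation
(called as hyperDMRs) and 3 of those have a down-regulated gene whose TSS
lies within 200 bp. Each downstream object is a tibble:

```r
glance(report$enrichment)
#> # A tibble: 1 × 7
#>   n_bins  n_de n_perm peak_bin_left peak_bin_right peak_ratio peak_z
#>    <int> <int>  <dbl>         <dbl>          <dbl>      <dbl>  <dbl>
#> 1     16     3    200          -250              0       11.8   5.98
```

The observed/expected curve peaks in the bin just upstream of the TSS
(−250..0 bp): down-regulated genes carry hyperDMRs in their promoters ~12×
more often than random expressed genes, exactly where the generator
planted them. `autoplot(report$funnel)`, `autoplot(report$enrichment)` and
`autoplot(report$deciles)` draw the standard figures.

A thin command-line wrapper ships in `inst/cli/rddm-pipeline.R`
(`simulate` and `run` subcommands) for shell use.

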
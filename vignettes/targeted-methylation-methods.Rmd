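---
title: "Methods: targeted RdDM analysis with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted RdDM analysis with synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddmtarget)
```

## The scientific setting

RNA-directed DNA methylation (RdDM) is the plant pathway that deposits
cytosine methylation under the guidance of small RNAs. Two plant-specific
polymerases divide the labour: Pol IV seeds 24-nt siRNA biogenesis, and
Pol V produces chromatin-bound scaffold transcripts that recruit the
downstream machinery, culminating in DRM2-mediated methylation in all three
sequence contexts (CG, CHG and CHH, where H is A, T or C).

Fusing RdDM components to an artificial zinc finger (ZF) tethers the
pathway to chromatin. Because the ZF binds promiscuously at thousands of
off-target loci, the binding-site universe becomes a natural experiment:
at which bound sites is Pol V recruited, where does that recruitment ignite
de novo 24-nt siRNA production, where does methylation actually accumulate,
is that methylation heritable once the transgene segregates away, and does
promoter-proximal methylation repress the neighbouring gene? This package
implements that analysis chain as a tested pipeline, together with a
seeded synthetic-data generator so every stage can be exercised against a
known truth.

## The analysis chain

**Methylation quantification.** Per-cytosine methylation is `#C/(#C+#T)`
from bisulfite counts. Context is read 5'→3' on the cytosine's own strand
from the two downstream bases. Reads carrying a run of more than 3
consecutive methylated CHH calls are removed as bisulfite-conversion
failures; the run is counted over the read's CHH calls in order, because a
failed conversion affects every cytosine and intervening CG/CHG calls
should not rescue a read. Amplicon (BS-PCR) analyses discard cytosines
under 20 reads; whole-genome analyses apply no per-cytosine floor. Region
summaries pool counts (coverage-weighted) rather than averaging
per-cytosine ratios, matching the pooled-count testing used for DMR
calling and behaving sensibly at low coverage.

**Anchored DMR calling.** 100-bp windows tile each binding site plus 1-kb
flanks (windows are anchored to the site universe, not genome-wide).
Within a window, methylated/unmethylated counts are pooled per group and
compared with a two-sided conditional exact test; windows with fewer than
4 covered cytosines in either group are skipped. Hypermethylated windows
require a methylation difference of at least 0.4 (CG), 0.2 (CHG) or 0.1
(CHH) at q < 0.01 (Benjamini–Hochberg within context). Retained windows
merge when their gap is strictly under 200 bp, with the merged difference
recomputed from pooled counts over the union; per-context region sets are
then combined with the same gap rule, recording contributing contexts.
For high-confidence de novo CHH regions, DMRs whose control CHH level
exceeds 0.05, or that touch a tRNA interval, are filtered out.

**Count statistics.** All two-group count comparisons (ChIP, siRNA bins,
RNA) share one engine: median-of-ratios size factors; log2 fold changes
from normalised group means with a pseudocount of 1 (avoiding infinities
at zero); p-values from a two-sided conditional exact test on the 2×2
table of pooled feature counts versus pooled library remainders; BH
q-values across the feature family. The exact test replaces the packaged
negative-binomial tests used in the original analyses because it is fully
specifiable and oracle-verifiable: tests verify it against complete
enumeration over all 2×2 tables with margins ≤ 12 and against
`fisher.test`. The cost of this substitution is known and documented: a
conditional exact test assumes (conditionally) binomial sampling, so with
strong between-replicate overdispersion its p-values are anticonservative.
The generator's default dispersion (0.01) represents modest pooled-library
noise under which the null calibration holds empirically (the suite checks
q < 0.05 calls on null simulations stay under 5% plus Monte-Carlo error),
and every published decision rule also gates on a fold change (>2, >4),
which the suite shows drives null call rates to essentially zero. A
precomputed-size-factor hook (`sf` argument) allows plugging a different
test later.

**Site classification.** Peaks are retained when fusion/control normalised
signal strictly exceeds 2-fold (pseudocount 1). Pol V recruitment is
deliberately inverted: a site is called *not* recruited when ZF-fusion
ChIP exceeds Pol V ChIP by more than 4-fold at q < 0.05; all other bound
sites count as recruited. A site produces siRNAs when at least one of its
100-bp bins passes fold > 4 and q < 0.05, with BH computed jointly across
all bins of all sites (a single family; no site-level selection bias); a
stricter "≥ 2 bins" variant sits behind the `min_bins` flag. The funnel
counts sites satisfying the ordered flags jointly (bound → Pol V → siRNA →
hyperDMR → proximal repressed gene); any flag subset works, e.g. dropping
the Pol V level for a Pol IV fusion.

**Heritability.** CG-context regions are ranked by methylation difference
(fusion − control), split into deciles (decile 1 = largest differences;
ties broken by coordinate; bin sizes differ by at most one), and a region
is heritable when the transgene-segregated plants retain at least a 0.10
CG gain over control. A 1e-9 tolerance keeps a gain of exactly 0.10 from
being lost to floating-point arithmetic.

**Expression integration.** RPKM quantifies expression; differential calls
use fold > 2 at q < 0.05 in either direction. Signed TSS distances are
negative upstream in the gene's own orientation, zero on overlap; the two
reference cases fix the edge arithmetic (upstream gap = TSS − region end;
downstream gap = region start − TSS), which makes reflection equivariance
exact only up to 1 bp — an unavoidable half-open-interval artefact. The
observed/expected curve counts regulated genes with a hyperDMR in each
250-bp distance bin over ±2 kb and divides by the mean of the same count
over seeded permutation draws of equally many genes from the expressed
universe (uniform, without replacement). The original work cites an
unspecified published algorithm for this step; label permutation is the
standard nonparametric null preserving the gene count, and its fidelity to
the cited algorithm is unknown. Because a ratio explodes in bins whose
expectation is near zero, the curve's *peak* is defined by the permutation
z-score `(observed − expected)/sd(permutations)`; the ratio is still
reported per bin.

**Phenotype.** Plants flowering with 20 or fewer rosette-plus-cauline
leaves are early flowering; 21 or more, late.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: 5 chromosomes × 400 kb
of uniform random DNA, 500 planted motif sites (12-bp motif written at the
site centre on a random strand) laid out on a jittered grid so neighbouring
flanks stay disjoint; truth flags nested as hypermethylated ⇒
siRNA-producing ⇒ Pol V-recruited ⇒ bound. Defaults: 90% of bound sites
recruit Pol V (matching the observed high recruitment efficiency), 20% of
recruited sites produce siRNAs and 50% of those gain methylation. The
producing/hyper fractions are desk-scale choices: the genome-scale analysis
this emulates found ~10% siRNA production and ~46% hypermethylation, which
at 500 sites would leave ~20 hypermethylated regions — too few for decile
statistics to mean anything. Counts are negative-binomial with one shared
dispersion per assay (0.01; the original work states none); per-cytosine
methylation is Binomial(Poisson coverage, baseline + planted gain), with
baselines CG 0.05 / CHG 0.03 / CHH 0.02 and mean gains CG 0.5 / CHG 0.3 /
CHH 0.2 extending 150 bp beyond each site. A configurable fraction of
reads (0.5%) fail conversion and report every cytosine methylated — the
read-level simulator gives the consecutive-CHH filter something real to
remove.

Planted gains scale with site accessibility (0.9–1.3× the mean), and the
most accessible tenth of hypermethylated sites is boosted to 1.5× so the
top gain decile is a distinctly strongest tier rather than a noise
ranking — in real data, decile-1 loci are qualitatively the
strongest-targeted sites. Heritability flags (60% of hypermethylated
sites) are interleaved evenly across the gain ranking (Bresenham), so any
contiguous gain window carries the same 60%; segregant plants retain the
full CG gain at heritable sites and revert to baseline elsewhere. ChIP
matrices append 4× background features because median-of-ratios
normalisation needs unenriched features to anchor on — at genome scale the
background provides that anchor implicitly. 80% of hypermethylated sites
get a gene planted with its TSS 20–180 bp downstream; such genes are
repressed 4-fold in the fusion line. All randomness flows from one seed
through named sub-streams, so adding a component never perturbs another
and identical configurations reproduce bitwise.

Not emulated: raw reads and alignment artefacts, PCR duplicates, genomic
repeat structure and pre-existing heterochromatin, chromatin-accessibility
tracks, linkage between assays' noise, and biological replicate effects in
bisulfite data (one pooled library per genotype, as in typical WGBS).
Passing recovery tests on this generator therefore demonstrates that the
pipeline's logic and thresholds behave as specified under the assumed
noise models — not that the thresholds are optimal for any particular real
dataset.

## Numerical and design choices

- Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and cytosine reports (1-based) convert only at file boundaries.
- "Within 200 bp" merges are strict (`gap < 200`), consistent with the
  companion wording "less than 200bp"; the gap is exposed as a flag.
- All fold thresholds are strict (`> 2`, `> 4`), FDR thresholds strict
  (`< 0.05`, `< 0.01`), and the DMR difference thresholds inclusive
  (`≥ 0.4/0.2/0.1`) so a window at exactly the stated difference counts.
- Hyper-only DMR calling is the default; hypomethylation support exists
  behind the `hypo` flag but is untested against published numbers.
- Degenerate inputs: empty p-vectors return empty q-vectors; windows with
  zero covered cytosines are skipped, not scored; regions with undefined
  levels are excluded from heritability denominators; sites without bins
  are non-producing with a warning; all-zero features get p = 1 and
  log2FC = 0.
- Decile ties break by (chromosome, start); bin sizes differ by ≤ 1.
- The DMR caller's defaults (CG 0.4 / CHG 0.2 / CHH 0.1, q < 0.01, ≥ 4
  cytosines) realise the "stringent criteria" of the methylome-analysis
  lineage this follows; every threshold is a `pipeline_thresholds()` field
  and is logged in the report for audit.

## Problem sizes

The test suite and acceptance script run: exhaustive exact-test
verification over all 2×2 tables with margins ≤ 12 (~5,500 tables); BH
rejection sets on 1,000 random p-vectors; 20 seed-swept null datasets of
~1,980 windows each for DMR null calibration; single null datasets of 200
sites (ChIP, siRNA) and 200 genes (expression) for classifier calibration;
and one full recovery run at the default 500-site conditions. These sizes
were chosen so the complete chain, including the synthetic genome, runs
comfortably on a laptop core in minutes.

## Known limitations

- The conditional exact test is anticonservative under strong
  overdispersion; interpret q-values on real, highly variable replicates
  with care, or supply a different test through the hooks.
- The observed/expected null permutes gene labels uniformly; it does not
  preserve gene length, expression level or chromatin context, any of
  which could matter in real data.
- The generator plants rectangular methylation gains; real RdDM spreads
  with distance-decaying profiles, so window-level power at region edges
  will differ on real data.
- Motif scanning counts exact-window mismatches only; no PWM scoring.
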
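---
title: "Identifying injury-responsive cis-regulatory elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying injury-responsive cis-regulatory elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdar)
```

# Scope

`atacdar` implements a multi-omic procedure for finding cis-regulatory
elements (CREs) whose chromatin accessibility responds to peripheral nerve
injury in sensory-neuron tissue, together with the downstream integration and
assay arithmetic such a study uses: ATAC-seq insertion-site processing and
simplified peak calling, an H3K4me1-constrained reproducible consensus region
set, a negative-binomial differential-accessibility test, nearest-gene
annotation with RNA-seq concordance, known-motif enrichment, protein
microarray Z-score scoring, and small calculators for luciferase and
ChIP-qPCR readouts. A synthetic-data module generates every input with
planted ground truth, so the whole chain is testable end to end without any
sequencing data.

# Coordinate conventions

All internal coordinates are 0-based half-open `[start, end)` — the BED
convention shared by every file format the package reads or writes. Printed
genome-browser spans (`"chr15:46,281,215-46,281,898"`) are 1-based inclusive
and are converted only at the `parse_region_string()` /
`format_region_string()` boundary; under that convention the width is
`B - A + 1`. Published coordinate spans are not perfectly consistent about
this (+1) rule, so both conventions are first-class and none is silently
assumed. Book-ended intervals (`end == start` of the next) are merged by
`merge_overlapping()`, matching the usual semantics of pooling peak lists
across samples.

# ATAC signal model

A sequenced ATAC fragment is bounded by two Tn5 transposition events. Because
Tn5 inserts as a dimer and duplicates 9 bp of target sequence, the read 5'
ends sit 4–5 bp away from the insertion centre; `fragments_to_insertions()`
applies the standard +4 (plus strand) / −5 (minus strand) correction. Both
fragment ends are treated as independent 5' ends — the left end as a
plus-strand end at `start`, the right end as a minus-strand end at `end` —
giving insertion positions `start + 4` and `end − 5`. Whether the correction
should be applied per-end or per-mate is genuinely ambiguous in most write-ups;
per-end is standard practice and is what we implement. Events shifted off a
chromosome edge are dropped and counted, so conservation
(`2 × fragments = events + dropped`) is exact and assertable.

Downstream representations:

* `recenter_insertions()` extends each event ±75 bp so the insertion sits at
  the centre of a 150-base pseudo-read (peak-caller input and track export);
  windows clipped at chromosome edges are flagged.
* `binned_coverage()` assigns each event to exactly one 300-nt bin by its
  single-base position (`pos %/% 300`). Bin totals therefore equal event
  counts exactly — we deliberately do *not* count 150-bp overlaps into bins,
  which would double-count at bin boundaries and break conservation.
* `group_average_track()` concatenates a group's samples and downsamples the
  pool to a common target, mirroring how browser tracks are equalized for
  depth; `normalize_per_million()` + `difference_track()` produce the
  injured-minus-naive difference track, which is antisymmetric by
  construction.

## Simplified peak caller

`call_peaks_simple()` stands in for a full peak caller with a defined,
dependency-free procedure: per-bin counts are tested against a Poisson rate
`lambda = max(genome-wide mean, local 10 kb mean)` (a single-level,
MACS-style local background), upper-tail p-values are Benjamini–Hochberg
adjusted genome-wide, significant bins within one bin of each other are
merged, and the summit is the centre of the highest-count bin. This is not a
MACS2 reimplementation; it is calibrated (the significant-bin fraction on
homogeneous noise stays below the FDR target) and monotone in `q_max`,
which is what the downstream consensus logic needs.

# Consensus regions and the differential test

Candidate loci are the merged union of all samples' peaks. A locus is kept
when at least `min_support_per_group = 2` samples support it *in every
group* (`mode = "each_group"`), the stringent reproducibility rule requiring
a peak in both injured replicates and 2 of 3 naive replicates when group
sizes are 2 and 3. Because published descriptions of "reproducible regions"
are ambiguous, an `any_group` mode is provided as configuration.
`subset_by_mark()` then keeps loci with ≥1 bp overlap of merged
H3K4me1-enriched regions — the step that turns accessible chromatin into
candidate CREs. Both filters are pure intersections, so their order does not
change the result on data where marks span whole peak clusters; we assert
this on synthetic data.

Counting (`count_matrix()`) uses insertion positions with half-open region
bounds, consistent with binning. Normalization is the median-of-ratios
estimator over features with all-positive counts, rescaled to geometric mean
1, with a total-count fallback.

`nb_group_test()` models normalized counts per region as negative binomial
with a common dispersion across groups:

* dispersion: pooled method of moments,
  `disp = Σ_g (n_g−1)(v_g − m_g ξ) / Σ_g (n_g−1) m_g²` with
  `ξ = mean(1/size_factor)`, floored at 1e−8 — defined and dependency-free,
  with no trend shrinkage;
* effect: `log2fc = log2((m_cci + 0.5) / (m_naive + 0.5))`, the 0.5
  pseudo-count stabilizing empty groups;
* test: Wald statistic `log2fc / SE` with the delta-method standard error,
  referred to a t distribution with `n1 + n2 − 2` degrees of freedom.

The t reference is a deliberate small-sample choice: with 3 vs 3 samples a
normal reference rejects ~13% of null regions at nominal 5%, while the t
reference stays inside [0.03, 0.07] across the count regimes we simulate
(means 20–500, dispersions 0.02–0.3). Calibration-by-simulation, not
fidelity to any particular tool's internals, is the quality bar here. The
permissive raw `p < 0.05` threshold defines the reported direction
(increased/decreased/ns), reflecting the view that single regions contribute
weakly to the phenotype; BH q-values are always reported alongside.
All-zero regions get `p = 1`, `log2fc = 0`.

`sample_qc()` gives PCA on centred `log2(normalized + 1)` values, Pearson
correlations, and average-linkage clustering on `1 − r` — the standard
checks that treatment groups separate.

# Annotation and expression integration

`classify_feature()` assigns one class per region by its midpoint with
priority promoter > exon > intron > intergenic. The promoter window is
−1000/+100 bp around the TSS, oriented by strand — a conventional default,
configurable because "promoter" is rarely defined explicitly. Midpoint
classification guarantees a unique class for regions straddling boundaries.
`nearest_tss()` anchors distance at the region midpoint against gene TSSs
(not gene bodies), signed positive downstream in the gene's orientation,
ties broken toward the lexicographically smaller gene id.

`integrate_expression()` joins each region's nearest gene to its DE call and
derives concordance (`acc_up_expr_up`, `acc_down_expr_down`, `discordant`,
`none`, with `absent` expression for unmatched genes). Since several regions
can share a nearest gene, `concordance_counts()` reports regions and
distinct genes separately — the "109 regions near 79 genes" shape.

# Differential expression

`filter_low_counts()` keeps genes with >0 reads in every sample.
`de_test()` reuses the NB Wald machinery (size factors by median-of-ratios,
BH adjustment); `classify_de()` applies the strict thresholds
`q < 0.05` and `|log2fc| > 0.5`. Where published thresholds conflict
(an abstract-level `p < 0.01` versus a methods-level `q < 0.05`), the
methods-level value is the default and both are plain arguments. Note that
BH q-values legitimately change when the tested gene set changes, so
filtering interacts with calls only through the adjustment, never through
per-gene p-values — asserted in the tests with size factors held fixed.

# Motif enrichment

Known-motif analysis only (de novo discovery is out of scope). PWMs come
from JASPAR text (`read_jaspar()`), get a 0.001 per-cell pseudo-count, and
are scanned as log2-odds against a background base composition.
`score_threshold_dp()` computes the *exact* distribution of the window score
under the background model by discretizing per-position scores to
`delta = 0.01` bits and convolving across positions; the hit cutoff is the
smallest support value whose upper tail does not exceed `threshold_p`
(1e−4 by default). Both strands are scanned (the reverse strand via the
reverse-complemented matrix); windows containing `N` are skipped.

Sequences are 200-bp windows centred on region midpoints.
`enrichment_test()` counts regions with ≥1 hit and applies a one-sided
binomial test with the background hit fraction as null proportion — the
classic known-motif statistic — with a hypergeometric p-value reported
alongside for explicit finite backgrounds, and BH across motifs. The
background is user-supplied or GC-matched sampling from non-differential
consensus regions (`gc_matched_background()`); because any given tool's
background construction is undocumented, specific published motif q-values
are not reproduction targets.

# Protein-microarray scoring

Raw spot intensity is `F/B` (foreground over background medians), with `B`
floored at 1 to avoid blow-ups on dark spots. `local_normalize()` divides by
the median of the 8-connected neighbouring probes (5 or 3 at edges/corners;
ring radius configurable), removing spatial gradients. The noise
distribution is taken as all valid non-control spots' normalized intensities
with the top 5% trimmed — binders are rare bright outliers and would
otherwise inflate the noise spread; `Z = (R' − mean)/sd` per array. A
protein (2 spots per array × dye-swap pair = 4 spots) is a hit only when
*all four* Z-scores strictly exceed 3.0. `T7`-prefixed control probes are
excluded from the noise model and never callable. The whole chain is
scale-invariant: multiplying every F and B by a constant changes nothing.
The neighbourhood definition and noise construction are exposed as
parameters because they are conventions, not published specifications; the
published hit lists are therefore not reproduction targets.

# Assay calculators

`relative_activity()`: per-well Firefly/Renilla ratios, construct mean over
empty-vector mean, SEM from construct replicates only (empty-vector
variability is not propagated, matching the usual "mean fold ± SEM"
presentation). `percent_input()`: dilution-adjusted ΔCt with efficiency
fixed at 2.0 (no standard-curve correction). `fold_enrichment()`: IP over
IgG percent input, mean ± SEM over replicates. Both qPCR calculators are
invariant to a constant Ct offset.

# The synthetic-data generator

The generator emulates the statistical structure of the study, not its
scale:

* **Genome/genes** — 2 chromosomes × 2.5 Mb; 200 non-overlapping genes with
  2–4 exons placed in evenly spaced slots.
* **Accessibility** — 300 regions (300–600 bp) in evenly spaced slots; each
  sample draws exactly `depth = 2×10^5` fragments, 50% uniform background
  and 50% allocated to regions (Gaussian around centres, sd = width/4, which
  yields unimodal, peak-caller-friendly pileups). Fragment lengths mix
  nucleosome-free (~80 bp) and mono-nucleosome (~200 bp) modes; only the
  ends matter downstream.
* **Planted effects** — 10% of regions are differential with alternating
  direction; increased regions are 3× more accessible in the injured group,
  decreased regions 3× in the naive group. Three samples per group.
* **Enhancer marks** — exactly `round(0.8 × 300)` regions are overlapped by
  a mark region (the region padded ±300 bp); planted differential regions
  are covered first, since being enhancer-marked is the premise of calling
  them CREs.
* **RNA** — negative-binomial counts; baseline means log-normal
  (log-mean `log 500`, sdlog 1), dispersion 0.01 (clonal cell-line
  replicates), and half of the differential regions' distinct nearest genes
  receive a ±2 log2-unit group shift matching their region's direction.
  These magnitudes were chosen so the planted truth is recoverable by the
  package's own DE procedure at n = 3 with BH correction — a generator whose
  planted effects are statistically invisible cannot validate anything.
* **Arrays** — 500 proteins × 2 spots × dye-swap pair on a 32-column grid,
  log-normal background (sdlog 0.3) and multiplicative foreground noise
  (sdlog 0.15); one planted binder at 10× foreground on all 4 spots;
  leftover positions are `T7_ctrl` probes.

Everything is deterministic under the design seed (each generator draws from
its own seed offset), per-sample fragment totals equal `depth` exactly, and
the planted truth round-trips through a sidecar TSV.

What the generator does *not* emulate: duplicate reads, mitochondrial
contamination, mappability structure, GC bias in counts, correlated
dispersion across regions, dye-specific bias, and real motif sequence
composition. Passing tests therefore demonstrate the pipeline's logic and
calibration, not robustness to those artefacts.

# Problem sizes and numerical choices

The default design (1.2 M fragments across 6 samples, 5 Mb genome, 2000
features in calibration simulations, 100-replicate null-array studies) runs
the full suite in minutes on one CPU; these sizes give Monte-Carlo error
comfortably inside the asserted bands. Tolerances used in tests: ±10% on
Monte-Carlo count ratios, [0.03, 0.07] on nominal-0.05 rejection rates,
discretization-exact checks for the PWM threshold, and exact equality for
conservation and bookkeeping invariants. Degenerate inputs are defined
errors, not silent results: zero-spread noise models, constant count
matrices, empty mark sets, malformed region strings.

# Known limitations

* The peak caller is a calibrated simplification; its boundaries are
  bin-quantized and its local background has one level.
* The NB test has no dispersion moderation across features, so it loses
  power at very low counts relative to shrinkage-based tools (it stays
  conservative there, not anticonservative).
* Nearest-TSS assignment is a heuristic for enhancer–gene linking; no
  chromatin-contact information is used.
* Motif enrichment depends on the background set; only the planted-motif
  behaviour on synthetic data is guaranteed.
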
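---
title: "Methods: read-depth CNV segmentation and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV segmentation and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgscohort)
```

wgscohort compares two tumor/normal whole-genome sequencing cohorts on
five axes: somatic copy-number landscape, loss of heterozygosity, clonal
architecture, mutation spectra, and candidate exogenous (microbial)
sequence content. Because the patient-level data such analyses run on are
controlled-access, every stage is paired with a synthetic-data generator
that plants known ground truth, so the whole pipeline can be exercised and
scored end to end.

## Read-depth CNV segmentation

The copy-number caller is a six-step signal-processing chain on paired
read-depth tracks:

1. Bin-level read depth is computed per sample for tumor and matched
   normal (the package consumes binned bedGraph; per-base tracks are
   aggregated on input).
2. The normal profile is scaled by the ratio of total tumor to total
   normal signal, so both carry the same total read depth:
   $\hat{RD}_n(i) = RD_n(i) \cdot \sum_j RD_t(j) / \sum_j RD_n(j)$.
3. The genome is divided into 3000-bp bins and signal summed per bin.
4. The log ratio $LR(b) = \log_2\!\left(\sum_{i \in b} RD_t(i) /
   \sum_{i \in b} \hat{RD}_n(i)\right)$ is computed per bin. Bins where
   either total is zero have no defined ratio; they are masked, excluded
   from smoothing windows, and split segments.
5. The noisy LR track is smoothed with a centered sliding median:
   each bin is replaced by the median of the bins within `half_window`
   on either side (default 500, a 1001-bin ≈ 3-Mb window), truncated at
   chromosome ends.
6. Maximal runs of constant smoothed LR become segments; each segment's
   log ratio is then recomputed from the raw binned totals over its span
   (not as the mean of smoothed values). Segments with LR > 0.2 and
   length > 100 kb are gains; LR < −0.2 at the same length, losses;
   everything else neutral. All inequalities are strict, so a segment
   exactly at a threshold is neutral.

**Resolution limit of the sliding median.** A centered median with
half-window $w$ maps any event occupying fewer than $w+1$ bins exactly to
the background level: the event's bins can never form a majority of any
window, so the median on every window is a background value and the event
leaves no trace in the smoothed track. With the default
`half_window = 500` at 3000-bp bins, only events of at least 501 bins
(≈ 1.5 Mb) survive smoothing; for those, boundary recovery on noiseless
bin-aligned data is exact at bin resolution (every window centered inside
the event holds an event majority, every window centered outside a
background majority). This is an inherent property of the chosen smoother,
not an implementation artifact: the pipeline recovers planted events of
all sizes exactly once `half_window` is matched to the scale of interest
(the test suite demonstrates precision = recall = 1.0 at
`half_window = 20` for 150-kb events). The default follows the
conventional 1000-bin window for arm-scale events; users targeting
sub-megabase CNVs should reduce `half_window` accordingly, or rely on a
dedicated segmentation caller and use `intersect_calls()` to keep the
events both approaches agree on.

**Constancy tolerance.** Runs are grown while smoothed values stay within
`tol = 1e-9` of the run's first value. Medians of identical windows are
bit-equal, so the tolerance only guards floating-point noise; it is
configurable but was not chosen for any particular dataset.

**Total-signal coupling.** Because step 2 forces the totals to agree, a
genome carrying net gains slightly depresses the log ratio everywhere else
(and vice versa) by $\log_2(1+\delta)$, where $\delta$ is the planted
events' share of total signal. On the synthetic genomes used in the tests
this shift is below 0.07 log2 units and does not move any planted event
across a call threshold; on real data it is the expected behavior of the
published normalization.

## Cohort frequency comparison and the randomization null

Per-sample gain/loss calls are projected onto a fixed 1-Mb genome grid;
a bin counts for a sample if any segment of that type overlaps it by at
least 1 bp (a segment straddling a boundary counts in both bins; no
minimum overlap fraction is imposed — the simplest reading of binned event
frequency). Each (bin, type) yields a 2×2 table of samples with/without
the event per cohort, tested with the two-sided Fisher exact test
(probability-mass rule). Significance defaults to raw p < 0.05, with
Bonferroni adjustment available as an option; the two conventions are both
exposed because published peak counts and figure captions differ on this
point, and the package does not attempt to resolve that discrepancy.

The randomization null shuffles cohort labels (group sizes preserved),
re-runs the full map-then-test path per shuffle on the fixed per-sample
calls, and summarizes the per-iteration significant-peak counts
(median/min/max over 1000 iterations by default). Re-testing fixed calls
under shuffled labels matches the design of mixing samples and randomly
reassigning them to two groups; segment calls are per-sample quantities
and do not depend on labels, so re-deriving them per shuffle would be a
no-op. Within one run, Fisher p-values are memoized by count table — a
pure-function cache that cannot change any result, only avoid recomputing
identical tables.

With 20 vs 23 samples the per-bin event counts can only take 21 × 24
values, and under exchangeability the observed count is one more draw from
the null's distribution, so the observed value falls inside the null's
min–max range in all but ≈ 2/1001 of replicate experiments. The test
suite verifies this calibration over 20 seeded replicates on a 50-Mb
two-chromosome genome (small enough to keep 20 × 1000 full pipeline
iterations within a few minutes on one core, large enough for 50 map
bins per event type).

## LOH calling

A site is loss of heterozygosity when it is heterozygous in the normal
and effectively homozygous in the tumor. Observed allele fractions are
never exactly 0.5 or 0/1 at finite depth, so the normal-side criterion is
carried by the genotype call and the tumor-side criterion by a tolerance:
tumor alternate-allele fraction ≤ `af_tol` or ≥ 1 − `af_tol` (default
0.02) at depth ≥ `min_tumor_depth` (default 10). At mean depth 40 and
`af_tol = 0.05`, a true LOH site fails only if the tumor depth drops
below 10 (Poisson probability ≈ 10⁻⁹) and a balanced het site false-calls
only if ≤ 2 of ~40 reads carry one allele (binomial probability ≈ 10⁻⁹),
which is why recovery against planted truth is essentially perfect.

## Clonal architecture

* **MATH score**: 100 · 1.4826 · MAD(VAF) / median(VAF), the
  MAD-over-median dispersion on the percentage scale, using the
  1.4826-scaled MAD convention of the MATH literature. Scale-invariant
  and ≥ 0.
* **Input filters**: somatic SNVs with VAF > 0.6 are removed before
  clustering (likely inflated by copy-number loss), along with sites
  below 14× depth; for tree building, SNVs inside segments with
  |log2 ratio| > 0.2 **and** segment p < 0.01 are removed (records with
  no overlapping segment are kept — the conjunction must hold to drop).
* **Clone count**: a 1-D binomial mixture on (alt, depth) fitted by EM
  for k = 1…5 with 10 restarts from quantile-spread initial means and a
  small seeded jitter, choosing k by BIC (−2·loglik + (2k−1)·log n). This
  is an explicit stand-in for full VAF-clustering tools: same inputs and
  filters, deliberately simpler model. It recovers planted k reliably
  when clone VAFs are separated by ≥ 0.15 at depth ≥ 80 with ≥ 150 SNVs
  per clone; closely spaced or low-coverage clones merge, as with any
  finite-mixture criterion.
* **Tree topology**: a tree is *linear* when every node has at most one
  child (a single lineage; the one-node tree is vacuously linear),
  *branching* otherwise. Trees are consumed as parent vectors (inference
  is out of scope); validation enforces a single root, acyclicity and
  connectivity.
* **Cohort comparison**: per-sample binary summaries (clone count = 1;
  tree is linear) go into a 2×2 Fisher table.

## Mutation spectra and signature weights

Spectra are counted over pyrimidine-centered classes (6 substitution
classes, or 96 trinucleotide classes ordered by substitution, then 5′,
then 3′ flank); purine-reference mutations are reverse-complemented
together with their context. Signature fitting minimizes squared error
between the observed 96-class spectrum and a non-negative combination of
reference-signature columns under a total-weight budget of 1 (non-negative
least squares; if the unconstrained optimum exceeds the budget the fit is
re-solved with a heavily weighted sum-to-one row). Weights below
`trim = 0.06` — the documented default of the tool this step stands in
for — are zeroed and the fit repeated on the surviving signatures. The
reference matrix is user-supplied; tests use a small synthetic 96×4
reference, so no proprietary signature file ships with the package.

## Exogenous-read filtering and taxonomy assignment

Host filtering removes reads with any *qualifying* host alignment
(mismatch rate ≤ 5 per 100 bp), reads overlapping host repeat sequence,
and host multi-mappers. `host_hits` counts qualifying alignments, so a
read whose only host evidence is a high-mismatch alignment is retained —
the filter's goal is a read set confidently *not* of host origin, so any
qualifying hit is disqualifying. The published 200-location search cap is
directionally ambiguous; reads above the cap are removed by default
(conservative) with `above_cap = "retain"` available. Surviving reads are
assigned to the lowest common ancestor of the leaves their zero-mismatch
exogenous hits map to; per-taxon counts roll up to ancestors (the root
count equals the number of assigned reads) and per-taxon presence/absence
is compared between cohorts by Fisher test.

## The synthetic-data module

Every generator is a pure function of its parameters and one global seed
(submodule seeds are derived by labeled hashing, so adding a generator
never perturbs another's stream). What they emulate — and what they do
not:

* `gen_rd_profiles`: binned depth around `base_depth` with Gaussian noise
  on bin totals (sd = `noise_sd`·√`base_depth`; a Poisson mode exists for
  count-level realism). No GC or mappability waves, no replication-timing
  structure — passing tests show the segmentation chain is correct, not
  that it is robust to those real-data artifacts, which the upstream
  normalization of a production caller would handle.
* `gen_genotype_table`: exact planted fractions (round(n·het), of which
  round(·loh) LOH) with binomial resampling of counts; no mapping bias or
  contamination.
* `gen_vaf_table`: diploid-heterozygous convention — a clone at cellular
  fraction f yields expected VAF f/2 (which is why the VAF > 0.6 filter
  marks copy-number-affected sites); depth Poisson, truncated ≥ 1.
* `gen_taxonomy_and_hits`: geometric level sizes from root to leaves;
  per-read truth is computed by brute-force path intersection,
  independent of the package's assigner.
* `gen_cohort_features` / `gen_segment_calls`: per-sample Bernoulli
  features and Poisson-count segment calls from one shared distribution,
  for null-calibration experiments.

Problem sizes in the tests (a 50-Mb, two-chromosome genome at 3000-bp
bins; 10,000 genotype sites; 200 SNVs per clone at depth 100; 1000
randomization iterations × 20 replicates; 10,000 sampled mutations for
the signature round trip) were chosen as the smallest scales at which
each statistical property is comfortably resolved on a single core.

## Known limitations

* The sliding-median resolution limit above: sub-(w+1)-bin events are
  invisible at the default window.
* The clone-count estimator is a stand-in; it matches the published
  filters, not the published clustering algorithm.
* The frequency map treats any ≥ 1-bp overlap as presence; a minimum
  overlap fraction, if one was intended, would lower boundary-bin
  frequencies.
* No purity or ploidy correction anywhere; log ratios are interpreted at
  face value.
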
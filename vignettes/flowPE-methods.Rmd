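---
title: "Genome size and partial endoreplication from flow cytometry: models and methods"
author: "flowPE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flowPE methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flowPE)
```

## The measurement model

Propidium-iodide flow cytometry reports, for each nucleus, a fluorescence
intensity proportional to its DNA amount. In tissues with **partial
endoreplication (PE)** — the rule in orchids — a nucleus that has passed
through `k` endocycles contains `2C + k·P` picograms of DNA, where `2C` is
the unreplicated somatic DNA amount and `P` is the size of the genome
fraction that re-replicates each round. A 1D histogram of such a tissue
therefore shows:

* one peak from the co-chopped **internal standard** of known 2C (here
  *Pisum sativum* 'Ctirad', 2C = 8.76 pg, or the secondary standard
  *Solanum pseudocapsicum*, 2C = 2.57 pg, itself calibrated by repeated
  measurement against the primary — see `calibrateSecondaryStandard()`);
* a **sample series** of peaks at `2C + k·P`, `k = 0..K` (commonly K = 3
  in ovary tissue, i.e. four sample peaks), with areas decaying in `k`;
* a low-fluorescence **debris** continuum from fragmented nuclei.

Each peak is modelled as a Gaussian whose standard deviation scales with
its position: `sd = cv · position`, with the coefficient of variation `cv`
(a standard cytometric quality measure) shared across peaks of one
preparation — the broadening comes from staining and instrument
variability, which act multiplicatively and identically on all nuclei in
the tube.

From the fitted peaks the two derived quantities are

* `2C = (sample 2C peak / standard peak) · standard 2C` — the calibrated
  ratio (`estimateGenomeSize()`);
* `P` = slope of the area-weighted least-squares line of peak position (pg)
  on endocycle index `k` (`estimateP()`). With exactly two sample peaks
  this reduces algebraically to the difference between the `2C + P` and
  `2C` peaks, which is the classical two-peak reading. The regression
  intercept re-estimates 2C and serves as an internal consistency check
  (an `intercept-mismatch` flag fires beyond 5% disagreement).

`P% = 100·P/2C` is the endoreplicated fraction of the genome. All pg
values are displayed to 2 decimals and percentages to 1 decimal.

## The joint (2C, P) marker

Two rules turn the pair (2C, P) into a delineation tool
(`jointClassify()`, `inferPloidy()`, `diploidPBand()`):

* **Ploidy follows P, not 2C.** Polyploids show P increased by the same
  fold as their ploidy: `ploidy = round(basePloidy · P / P_ref)` against a
  diploid reference `P_ref`. Diploid taxa share a narrow P band (< 4 pg by
  default) even across ~5-fold genome-size variation, so a 1.5× or 2× P
  shift is read as DNA-triploidy or -tetraploidy. The residual from the
  nearest integer fold, beyond `p_tol` (default 0.10), flags
  `ambiguous-ploidy`.
* **Homoploid divergence follows 2C at constant P.** An individual whose
  P sits at its taxon's fold but whose 2C deviates from the leave-one-out
  taxon mean by more than `gs_hybrid_dev` (default 0.15) is
  `homoploid-divergent` — the cryptic-lineage signal — and additionally
  `hybrid-suspect` when its 2C lies between its own taxon mean and another
  taxon's mean. The leave-one-out mean is used for flagging so an outlier
  cannot dilute its own reference; the reported deviation percentage uses
  the individual's value as denominator (a 23.8 vs 28.1 pg case reads as
  ~18%), and both are returned.

When no reference `P_ref` is configured, `deriveDiploidRef()` estimates it
by scoring every candidate reference (each observation at each plausible
fold) by the total relative distance of all observations to their nearest
integer fold, under the constraint that the smallest observed P sits at the
base fold (the reference level must be present in the data), with ties
broken toward the largest reference. This deliberately avoids assuming
that diploids are the majority — a median-based start point fails on
polyploid-rich collections.

## Peak detection and fitting

The route from histogram to peak list
(`detectPeaks()`, `fitPeak()`):

1. **Smoothing.** A moving-window quadratic (Savitzky–Golay) smoother,
   window 9 channels by default, on the 1024-channel linear histogram.
2. **Candidates.** Local maxima of the smoothed curve; ties between equal
   adjacent maxima resolve to the lower channel. Two candidates are
   treated as one peak unless (a) they are at least `2·cv` of their
   position apart (`cv` learned by fitting the tallest candidate first —
   no real pair can sit closer), and (b) the smoothed curve dips between
   them below 75% of the lower maximum *and* below it by more than ~1.5
   Poisson standard deviations on the smoothed scale. Without (b), counting
   noise on a broad low peak fragments it into several spurious maxima.
3. **Fitting.** Each candidate is refined by a weighted least-squares
   single-Gaussian fit (weights `1/max(count, 1)`, approximating Poisson
   variance) on a window of ±3 preliminary sd (from the half-maximum
   width), clipped at midpoints to neighbouring candidates so no window
   bridges two peaks. Fits whose sd rivals the window width are discarded
   as bridge artefacts; windows with fewer than five nonzero channels fall
   back to moment (centroid) estimates, which is what a delta-like
   noiseless peak produces. The reported area is the Gaussian integral,
   not the raw window sum.
4. **Quality gates.** Peaks with fitted area below `min_peak_events`
   (default 100) or cv above `cv_max` (default 0.10) are dropped with a
   logged reason. Peaks closer than `2·(sd₁+sd₂)` are flagged `merged`,
   never force-split.

## Role assignment and series refinement

`assignPeaks()` identifies the standard by elimination: each peak in turn
is excluded and the rest, ascending, must fit `2C + k·P` with per-peak
relative residual under `progression_tol` (default 0.02, chosen to accept
cv = 0.05 data while rejecting misassignments). Up to two trailing peaks
may be set aside when the full set fails — a merged last endocycle peak
must not invalidate a clean series. If several exclusions fit equally well
(inevitable with only two sample peaks, since any two points are
collinear), an expected-2C hint resolves the tie; otherwise the assignment
is refused rather than guessed. A sample 2C peak closer to the standard
than `2·(sd₁+sd₂)` raises an overlap error advising a secondary standard.

After assignment, `measureSample()` refits the whole sample series
**jointly** as a sum of Gaussians with one shared cv
(`minpack.lm::nls.lm`), anchored on the 2C and 2C+P peaks and with the
standard's fitted peak subtracted. This is the step that removes the bias
independent single-peak fits suffer from neighbouring tails (up to several
percent on P for large genomes, where consecutive peaks sit ~4 sd apart),
and it recovers trailing endocycle peaks that the detector merged, by
looking at the predicted `2C + k·P` positions. Guard rails — a component
sliding to its position bound, a refined series off the arithmetic
progression, a failed core component — revert to the unrefined peaks
rather than trusting a misconverged fit.

**Refusal policy.** A fitted "standard" peak whose cv exceeds 1.4× the
series cv is two unresolved peaks: the sample 2C riding on the standard.
Accepting it would shift every endocycle index by one and report a 2C off
by ~P. The measurement is refused with an overlap error advising a
secondary standard of different size — the same decision the original
workflow takes for *N. maculata*, whose genome size nearly coincides with
*Pisum*. In simulated reference cohorts this affects the few percent of
individuals whose drawn 2C lands within ~1 pg of 8.76 pg; a refusal is a
correct diagnosis, and recovery statistics are therefore quoted among
measured individuals with the refusal rate reported alongside.

## The synthetic-data generator

`simulateSample()` draws events from the mixture the analysis assumes:
multinomial component labels (debris fraction 0.05; standard fraction 0.3
of non-debris; sample peaks `k = 0..K` with geometrically decaying weights,
ratio 0.5), debris as an exponential truncated to the sub-standard range
(mean one fifth of the standard position — the simplest shape that
stresses detection), and Gaussian peaks with `sd = cv·mean`, cv defaulting
to 0.03 (typical of good plant preparations, within the usual 2–5% range).
The default 5,000 events match the usual acquisition minimum; 0.05 pg per
fluorescence unit places the largest reference genomes inside a
1024-channel axis. `simulateCohort()` draws per-individual (2C, P) from
zero-truncated normals at taxon means/sds (redrawing impossible P ≥ 2C up
to 100 times), and `neotineaReference()` supplies the published taxon
means used for validation cohorts. Seeds are explicit everywhere; a fixed
seed gives bit-identical events.

What the generator does **not** emulate: doublets and aggregates,
fluorochrome base-content bias, S-phase (intra-endocycle replication)
continuum, instrument drift, or 2D debris structure. Passing tests
therefore demonstrate correctness of the estimation machinery under the
stated model, not robustness to every instrument artefact; the relative
areas of endocycle peaks in real tissues are not published, so the decay
ratio 0.5 is a configuration default, not an estimate.

## Taxon summaries and letter groups

`summarizeTaxa()` aggregates per (taxon, ploidy, region/variant): means,
sample sd (n−1), `P%` always recomputed from the stored means (never
copied), deterministic row order, sd marked absent for singletons.
`tukeyGroups()` runs one-way ANOVA with Tukey HSD (Tukey–Kramer for the
very unbalanced group sizes, 2–106 in the reference data) via
`stats::TukeyHSD()`, then assigns compact letters by the insert-and-absorb
algorithm, letters ordered by ascending group mean — deterministic and
cross-checked in the tests against a brute-force pairwise
studentized-range oracle and against `multcomp::cld()`. Groups with fewer
than two observations are summarized but excluded from lettering (the
reference table letters only diploid lineages); zero residual variance
with unequal means separates all pairs. HSD is computed on individuals by
default (`summary$hsd_unit`), matching the per-individual measurement
table; a population-level unit is accepted in the configuration for data
aggregated beforehand.

## Configuration, determinism, degenerate inputs

All thresholds live in one validated YAML configuration (`readConfig()`):
binning (1024 channels — the common instrument default; the true
acquisition resolution is not published), gating ranges, detection
(`smooth_window`, `min_peak_events`, `cv_max`), the PE model (`p_mode`:
`regression` over all peaks by default, `first_two` for the strict
two-peak reading — the published procedure names the first two peaks, the
regression uses all available information and coincides with it at K = 1),
delineation thresholds, and simulation parameters. Unknown keys are
rejected so typos cannot silently fall back to defaults. Every pipeline
output carries a provenance header (tool version, configuration hash,
seed); identical configuration and seed give byte-identical outputs.
Degenerate inputs have defined behaviour throughout: empty event sets bin
to zero histograms, all-zero histograms raise a no-peaks error, gates that
exclude everything raise an empty-gate error, single sample peaks make P
undefined (an insufficient-peaks error), and a non-increasing series is a
model violation, not a negative P.

Validation problem sizes: the end-to-end recovery check simulates the full
349-individual reference cohort once (5,000 events each) and the
polyploid-series ploidy check uses nine individuals per seed across 20
seeds; per-module tests use single tubes. These sizes keep the complete
suite under a minute on one core while exercising every taxon pattern in
the reference table.

## Known limitations

* Heavily overlapped standard/sample peaks are refused, not deconvolved;
  resolving them requires re-running the tube with a different standard.
* Replicate runs per individual are averaged (the default aggregation);
  no within-individual variance model is fitted.
* The ploidy rule assumes the reference (diploid) level is present in the
  analysis group; a collection containing only polyploids of one series
  would be read one level low.
* Absolute genome sizes inherit the standard's calibration; no
  base-content (AT/GC) correction is applied.
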
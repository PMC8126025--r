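---
title: "Membrane profiling from FFE fractionation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane profiling from FFE fractionation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffeprof)
library(dplyr)
```

## The analysis problem

Free flow electrophoresis (FFE) separates microsomal membrane vesicles in a
laminar buffer film by net surface charge. A run yields 96 fractions along
an anode–cathode axis; adjacent fractions are pooled pairwise into 48
protein samples, and each sample is quantified by data-independent
acquisition mass spectrometry, giving a peak area per protein per sample
per biological replicate. Because each subcellular membrane carries a
characteristic surface charge, each compartment occupies a reproducible
band of samples: tonoplast vesicles run most anodic (samples 13–19, with a
smaller second population near sample 24), the ER splits between samples
18–20 and 23–25, Golgi/TGN, chloroplast envelope and the main mitochondrial
population co-fractionate around samples 23–25, thylakoids add a distinct
population at sample 20, and the plasma membrane runs most cathodic
(samples 24–30, peaking at 25).

The replicate-averaged, OD280-normalized, unit-sum abundance profile of a
protein across the analysis window — its *digital western* — can therefore
be read like an antibody western across fractions: the positions and
relative sizes of its abundance populations identify the membrane(s) it
resides in. `ffeprof` implements this chain end to end: pooling, window
selection, normalization, replicate averaging, marker-consensus
construction, correlation-based compartment assignment, one- versus
two-population detection, dual-localization and annotation-discordance
flags, plus a synthetic-run generator with known ground truth so every
stage is testable without raw instrument data.

## Preprocessing model

*Pooling is summation.* Pooling adjacent fractions physically combines
material, so pooled sample $s$ is the sum of fractions $2s-1$ and $2s$;
per-protein totals are conserved exactly. The OD280 trace pools the same
way.

*Window selection.* The analysis window is the largest contiguous run of
pooled samples with OD280 strictly above zero (ties resolve to the most
anodic run). With protein detected over fractions 15–70 this gives samples
8–35, i.e. 28 samples. A recorded trace always takes precedence over the
default; an explicit window can override both.

*Normalization order.* Peak areas are divided by the pooled OD280 of their
sample (abundance per unit protein) *before* replicate averaging, placing
normalization at the quantification level. Averaging first and normalizing
after gives the same profiles up to the per-sample scale, but applying the
division first keeps replicate dispersions on the normalized scale on
which all downstream comparisons happen.

*Zeros are data.* Exported quantification matrices report non-detections
as absent rows; readers materialize them as zero and replicate means
include them. Dropping zeros would bias two-population profiles toward the
better-covered population. Proteins undetected in a whole replicate are
counted and reported as a message, not removed.

## Compartment consensus profiles

A compartment's consensus is the element-wise **median** of its detected
markers' unit-sum profiles, renormalized to unit sum. The median is
deliberate: curated marker lists contain documented outliers — V-ATPase
subunit isoforms whose profile sits almost entirely in the cathodic
population while the rest of the tonoplast set runs anodic — and a mean
consensus would be dragged toward them. Marker coherence (median and
minimum pairwise Pearson correlation per compartment) is reported as
quality control; a marker correlating below 0.5 with its compartment's
median profile is listed as an outlier, and excluded from the consensus
only when `robust = TRUE` (off by default, mirroring the use of curated
lists as-is). Single-marker compartments have undefined coherence and are
reported as such.

## Assignment by profile correlation

Profiles are compared by Pearson correlation on unit-sum vectors over the
shared window — the standard protein-correlation-profiling choice, and
scale-free, so multiplying a raw profile by any positive constant leaves
scores unchanged. A protein is assigned to its best-scoring compartment
when the best score reaches `r_min = 0.8` and leads the runner-up by
`margin_min = 0.1`; otherwise it is *unassigned*. These thresholds are
configurable defaults chosen for this geometry, not empirical constants:
with the default templates the largest between-compartment correlation is
about 0.84, so a clean profile clears both bars while profiles caught
between two similar compartments (Golgi vs. chloroplast envelope, say)
fall to *unassigned* rather than being guessed. Exact ties are never
broken arbitrarily — the protein is unassigned with a tie flag. All-zero
profiles have undefined correlation and are unassigned.

## Population detection

`detect_populations()` decomposes a profile into abundance populations:

1. smooth with a centered **triangular** (1–2–1) moving average of width
   `smooth_width = 3`. The triangular kernel is used rather than a flat
   one because a flat window fills the 2-sample valleys that separate,
   e.g., the thylakoid population at sample 20 from the cathodic cluster
   at 23–24, merging genuinely distinct populations;
2. keep local maxima of the smoothed profile whose topographic prominence
   is at least `prominence_frac = 0.10` of the smoothed global maximum;
3. cut watershed basins at the smoothed minima between surviving peaks.
   The valley sample itself belongs to neither basin, which makes the
   decomposition exactly symmetric under profile reversal;
4. report each population at the *raw* within-basin maximum (smoothing is
   for segmentation only and can displace a narrow peak by one sample),
   with the raw basin mass as its share;
5. discard populations with mass below `mass_min = 0.15`.

The mass floor is a reporting guess, not an inference from data: it is set
so that the documented smaller tonoplast population (one fifth of the
template mass at sample 24) survives at default settings, while replicate
noise cannot conjure a population. Mass shares sum to at most 1.

## Dual-localization flags

Characteristic windows (contiguous samples where a consensus exceeds half
its own maximum) say *where* each compartment lives; native populations
(population detection applied to the consensus itself) say *how much* mass
each compartment natively carries there. A detected population maps to
every compartment whose window contains its peak; populations outside all
windows map to `none` (the fate of, e.g., an unbound soluble protein
running fully anodic in samples 8–14) and carry no dual evidence.

A protein is flagged dual when at least two of its populations map to
compartment windows and its best-correlated compartment cannot *explain*
the pattern: every population must lie within `pos_tol = 2` samples of one
of that compartment's native populations, and the observed mass attributed
to each native population must not exceed the native share by more than
`excess_min = 0.10`. Position alone cannot decide this, because several
compartments are natively bimodal and nearly all windows overlap in
samples 23–25; the mass test is what recognizes, say, a tonoplast protein
carrying 45% of its mass in the Golgi window where tonoplast natively
carries 20%. This mirrors how dual localization is actually argued from
fractionation profiles: not by the mere existence of a second peak, but by
a second population too large for the primary compartment's own shape.
The mass excess tolerance is set well above the replicate-noise scale of
basin masses (a few percent) and well below the default planted secondary
share (0.3).

Discordance flags compare the profile assignment with prior annotation,
preferring the high-confidence (experimentally verified) compartment over
consensus predictions; unassigned and unannotated proteins are never
flagged.

## The synthetic-data generator

The generator emulates the study geometry: 96 fractions, pairwise pooling,
three biological replicates, an OD280 trace positive exactly over
fractions 15–70, and per-compartment mobility templates. Each template is
a mixture of one or two discrete Gaussians evaluated at integer sample
indices and renormalized — the simplest smooth shape matching the
bar-profile look of digital westerns. Peak *centers* are fixed by the
marker windows listed above; peak *widths and mixture weights* are free
model parameters, chosen once so the eight templates are mutually
distinguishable at marker grade (largest pairwise correlation ≈ 0.84 over
the analysis window) and so that each template's secondary population
clears both the half-max window rule and the population mass floor. Where
the source material gives no ratio (the ER's two populations, the size of
the mitochondrial sample-20 shoulder) the split is a declared choice, not
a measurement.

Remaining generator choices, fixed once:

* **Noise** is multiplicative lognormal with CV 0.2 per
  protein × fraction × replicate cell, mean-preserving
  (`meanlog = -sdlog²/2`) — the standard model for MS peak areas. The
  within-replicate CV of SWATH quantities is not a reported value; 0.2 is
  a realistic default for peak-area quantification and is the package's
  own choice.
* **Missingness**: cells are zeroed with probability 0.02, matching SWATH
  non-detection semantics (zeros, not NA).
* **Abundance**: per-protein factors are drawn log-uniformly over two
  orders of magnitude, so normalization steps are exercised non-trivially.
* **OD280 trace**: a trapezoid — linear ramps over the first and last
  eight window fractions, flat plateau between, small lognormal noise
  (CV 0.05). The plateau keeps OD normalization non-trivial at the window
  edges without reshaping in-window population masses, so ground-truth
  mass shares survive preprocessing exactly in the noise-free limit.
* **Fraction splitting**: each pooled sample's mass is split between its
  two member fractions by a uniform draw in [0.4, 0.6]; pooling by
  summation undoes the split exactly.

*Planted duals.* A dual-localized protein is a 0.7/0.3 mixture of two
templates. Pairs are planted only when the two major peak centers are at
least 5 samples apart **and** the noise-free mixture is identifiable: its
population pattern, detected under strictened thresholds (1.5× prominence,
mass floor +0.03), must not be attributable to any single compartment
template under the same explanation test used at analysis time. This is a
closure property of the template geometry computed once at generation
time. It excludes pairs that are unresolvable in principle — mitochondria
plus ER co-locate at both 19–20 and 24, and a thylakoid + plasma-membrane
mixture reproduces the mitochondrial two-population shape almost exactly —
so the recovery experiments measure robustness to noise, not structural
confusability.

*What the generator does not emulate*: peptide-to-protein roll-up,
retention-time or spectral effects, correlated (batch) noise, abundance-
dependent noise, chimeric marker behaviour (every simulated marker is a
faithful copy of its template), or electro-kinetic physics. Passing
recovery tests therefore show that the pipeline's logic is correct under
its own generative assumptions — they do not certify performance on real
SWATH exports, where marker heterogeneity and correlated noise would
lower coherence and widen score margins.

## Problem sizes and determinism

The shipped tests run the generator at 8 compartments × 100 proteins with
3 replicates (about 230k quantification cells) for parameter-recovery
checks, 10 proteins per compartment for noise-free and discordance
checks, and 1,000 random 28-sample profiles for oracle equivalence of the
population detector — sizes chosen to exercise every code path in seconds
on a single core. All randomness flows from a single integer seed;
identical seeds give byte-identical output files.

## Known limitations

* Compartments whose templates co-locate within a couple of samples
  (Golgi vs. TGN vs. chloroplast envelope around samples 23–25) are
  separated here because the synthetic templates are exactly reproducible;
  on real data their assignment margins would be thinner and more proteins
  would legitimately fall to *unassigned*.
* The dual flag tests explanation against the single best-correlated
  compartment; a protein residing in three compartments, or in two
  compartments whose profiles co-locate, is reported by its populations
  but not flagged.
* Populations running anodic of all compartment windows (samples 8–14)
  map to `none`; no dedicated "unbound/soluble" class is modelled.
* No imputation, batch correction, or probabilistic (mixture-model)
  assignment is attempted; the package is deliberately a transparent,
  rule-based reading of profile geometry.

## Worked example

```{r example}
sim <- simulate_ffe_run(sim_config(n_proteins_per_compartment = 10, seed = 1))
dw <- digital_westerns(sim$quant, sim$od280)
loc <- localize_proteins(dw, sim_marker_set(sim$truth))
glance(loc)
localization_metrics(loc, sim$truth)
```

```{r plot, fig.width = 6, fig.height = 4}
plot_digital_western(dw, proteins = sim$truth$protein_id[1:2],
                     windows = loc$windows)
```
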
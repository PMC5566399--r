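---
title: "Estimating mutation and gene-conversion rates from autozygous segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation and gene-conversion rates from autozygous segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

An individual whose parents are k-th cousins carries autozygous segments:
intervals where both homologs descend from one haplotype of the shared
ancestral couple, separated by `M = 2k + 4` meioses. Within such a segment a
heterozygous genotype is either a de novo mutation (DNM) accumulated over
those `M` transmissions, a non-crossover gene conversion (NCO) that copied a
segregating allele from the homologous chromosome on one of the
transmissions, or a genotyping artifact. With

* `N` — corrected count of qualifying heterozygotes,
* `L` — summed autozygous, callable sequence across individuals (bp),
* `M` — length-weighted mean number of separating meioses,

the mutation rate per bp per generation is `mu = N / (L M)`. Each component
has its own estimation machinery, and each is validated against either an
exact oracle or a synthetic cohort with planted truth.

## Autozygous segments and the 10 Mb / 2 Mb filters

Segment calling is out of scope (segments are consumed, or simulated);
the filters that define the *analyzed* segments are not. Only segments of at
least 10 Mb enter the analysis: pedigree simulation on the bundled map shows
that segments this long arise in well under a tenth of pedigrees separated
by more than 10 meioses, so surviving segments overwhelmingly reflect recent
common ancestry. Each surviving segment is trimmed by 2 Mb at both ends
(`truncate_segments()`): segment callers over-run true IBD boundaries, and
adjacent IBD with an older common ancestor carries a higher heterozygote
density; the synthetic-cohort tests show the estimate is insensitive to
trimming beyond this scale but strongly inflated without trimming. `L` is
the intersection of the resulting cores with exome baits and a callability
mask (`compute_L()`), summed over individuals, so a genomic position
autozygous in k individuals contributes k bp of opportunity.

## Pedigree recombination simulation

`simulate_autozygosity()` gene-drops gametes through a single-loop cousin
pedigree. Crossovers per chromosome are Poisson with mean equal to the
genetic length in Morgans (Haldane model: no interference, no obligate
chiasma), positions are uniform on the genetic scale and mapped to physical
coordinates through the map's inverse, and the transmitted haplotype at the
chromosome start is chosen with probability 1/2. The bundled default map
(`default_genome()`) uses GRCh37 physical lengths with linear per-chromosome
sex-averaged genetic maps totalling ~35.9 Morgans; any piecewise-linear map
can be supplied as a TSV (`read_genetic_map()`). Sex-specific maps are not
bundled: averaging the sexes keeps the simulation deterministic in
configuration, and random sex assignment would only widen the
segment-length distribution slightly.

Two consequences of the Haldane choice are documented rather than hidden:
the long-segment tail is slightly heavier than under interference models, so
the fraction of 12-meioses pedigrees with a >10 Mb segment simulates to
~8.0-8.3% (interference-aware simulators report slightly under 8%); and
segment-length variances are marginally larger than real maps produce.

## Inferring the separating meioses

For each individual the number of separating meioses is inferred from the
segment-length distribution via three summary features of its >=10 Mb
segments — longest, mean, count — with a Gaussian-kernel nearest-centroid
classifier trained on simulated pedigrees (`build_training()`,
`classify_individual()`). Class weights are
`exp(-||z - z_class||^2 / (2 h^2))`, normalized; the hard assignment
`M*` is the maximal weight with ties broken toward the smaller meiosis
count (assuming a more recent ancestor yields the smaller, more conservative
mutation rate). The cohort value is the autozygous-length-weighted mean of
the per-individual posterior means (`weighted_mean_meioses()`), which is the
algebraically correct weighting because expected heterozygote counts are
proportional to `L_i M_i`.

Two honest limitations. First, the three features carry limited
information: third cousins have no >=10 Mb segment in ~65% of simulations
(fourth cousins ~91%), so third-versus-fourth discrimination is close to its
Bayes limit and per-class held-out accuracy is high only for the classes
(first cousins, and "fourth-or-beyond") that dominate the cohort's
autozygous mass — a Parzen class-density classifier achieves essentially the
same confusion pattern, confirming the limit is informational, not
algorithmic. Second, the bandwidth `h` does not affect `M*` at all (the
argmax is monotone in centroid distance); it only shapes the posterior
weights. We therefore calibrate `h` on what it actually influences: across
simulated full-genome cohorts, `h = 0.8` makes the length-weighted
posterior-mean meioses agree with the truth ledger to better than 0.01
meioses (it is ~0.13 low at `h = 0.5`, and high beyond `h = 1`). Classes are
not separable on very short genomes: on the 4 x 150 Mb test genome
(7.5 Morgans) no classifier can distinguish second from third cousins, so
meiosis inference is validated on the full 22-autosome map.

## Error model

`alpha` (probability a non-heterozygous genotyped site is called het) and
`beta` (probability a true het is missed) are estimated jointly from
duplicate-sample replication. Under Hardy-Weinberg prior `h = 2f(1-f)` and
independent errors between duplicates, the probability that a het call at
population frequency `f` replicates is

```
R(f) = (h (1-beta)^2 + (1-h) alpha^2) / (h (1-beta) + (1-h) alpha)
```

(`predict_replication()`), which tends to `alpha` at rare sites and to
`1 - beta` at common ones. Fitting the ~100-bin empirical curve is an
overconstrained two-parameter problem; `fit_error_rates()` minimizes the
count-weighted squared deviation with a deterministic 5 x 5 multi-start over
`(0.005, 0.3)^2` plus bounded refinement (`nlminb`, objective tolerance
1e-18), is exact on noise-free curves across `(0.001, 0.5)^2`, flags
boundary solutions (e.g. a degenerately perfect curve), and drops empty
bins rather than imputing them. Count weighting is the default; equal
weighting is available (`weights = "equal"`).

The false-negative rate is frequency-resolved (joint calling recalls rare
variants less reliably): an `fn_table()` carries per-MAF-band values, by
default 17% for singletons, 12% for rare variants and 7.9% above 10% MAF
(the intermediate value interpolates between the two anchored bands). An
independent check is the spike-in recall path (`spike_in_recall()`): planted
heterozygotes (each read switched to a predetermined alternate with
probability 0.5; transitions twice as likely as transversions) are passed to
a pluggable genotype caller — by default het iff >=2 alternate reads and
alternate fraction >=0.2 — and the missed fraction matches the binomial
closed form over the depth profile.

## Rate estimation and the MAF-threshold regression

The singleton estimator uses cohort singletons (`AC = 1`) inside the cores.
Two correction conventions are implemented because they genuinely differ:
`standard` computes `N0 (1-alpha) / ((1-beta) L M)` (remove false
positives, inflate for false negatives), while `paper` computes
`N0 (1-alpha)(1-beta) / (L M)`, the multiplicative form that reproduces the
published worked example (1.51e-8 from N0 = 1152, L = 9.46e9, M = 6.63,
alpha = 1%, beta = 17%). `standard` is the default and is the form validated
by planted-truth recovery; with the same inputs it gives 2.19e-8.

For the regression, `rate(f)` is computed on the grid `f = 0.10 ... 0.50`
(step 0.01) and regressed on `f` by OLS. The false-negative correction is
applied per call — each counted heterozygote is weighted
`1 / (1 - beta(MAF))` — rather than with a single per-threshold factor:
`N_f` mixes frequency bands (every singleton lies inside every `N_f`), and a
single-factor correction would push the intercept down by roughly the ratio
of the singleton to the common-variant recall (~10%). The per-call weighting
reduces to the single-factor formula when `beta` is constant and makes the
planted-truth recovery unbiased. The false-positive factor `(1 - alpha)` is
applied uniformly, treating `alpha` as the spurious fraction of emitted
calls; this matches how the correction enters the published arithmetic,
whereas in the replication-curve model `alpha` is a per-site quantity — the
two usages are kept deliberately distinct (see the generator below).

The slope converts to a conversion rate through the cumulative
heterozygosity of the cohort's site frequency spectrum,
`Pi(f) = sum_{MAF<=f} 2p(1-p) / callable bp` (`sfs_summary()`): a conversion
event at a segregating site produces a heterozygote with probability
`2p(1-p)` (the background haplotype and the donor allele must differ), so
heterozygotes of MAF <= f accrue at `c * M * Pi(f)` per bp and

```
c_hat = slope * (f_hi - f_lo) / (Pi(f_hi) - Pi(f_lo)).
```

For a neutral spectrum `Pi` is nearly quadratic in `f`, for which the OLS
slope over a symmetric grid equals this secant exactly, so `c_hat` is
unbiased under the generator's own model. One bias is intrinsic and
documented rather than corrected: conversions of alleles *below* the
regression window contribute a constant to every `N_f`, and extrapolating
the window line to `f = 0` retains the curvature term
`c * (Pi(f_mid) - f_mid * dPi/df)` — about +3.5% of `mu` under the default
conditions. This is a property of MAF-threshold regression itself (the
published analysis likewise notes its singleton and regression estimators
bracket the truth from opposite sides); tests therefore compare recovery
against bootstrap uncertainty rather than asserting exact unbiasedness.

Uncertainty comes from resampling individuals with replacement
(`bootstrap_se()`, and internally in `estimate_rates()`): individuals are
the exchangeable units; their segments and calls travel together. The
cohort SFS is held fixed across replicates (it is estimated from ~10^6
sites and its resampling error is negligible beside the count noise).

## The synthetic cohort generator

`generate_cohort()` produces the labelled data every other module is tested
against. Per individual: a relationship drawn from the configured mix, true
autozygous segments from the pedigree simulator, DNMs planted as
`Poisson(mu L_i M_i)` uniform over the autozygous genome, conversions
planted on a segregating-site panel with per-site probability
`c M_i 2p(1-p)`, boundary over-call (observed segment ends over-run the
truth by an exponential overshoot, mean 100 kb, with ~1.5 population
heterozygotes contaminating each over-called zone — emulating how an HMM
segment caller exits only after accumulating evidence), false positives
planted so that a fraction `alpha` of emitted calls is spurious, and
false-negative thinning by the per-band table. The site panel is a neutral
(1/k allele-count) spectrum calibrated to a target heterozygosity of
9.56e-4 per bp. Every emitted call traces to exactly one truth-ledger
entry; ledger conservation is asserted in the tests.

Defaults are the study conditions the estimators target: mu = 1.45e-8,
c = 8.75e-6 per bp per generation, alpha = 1%, the FN bands above, mean
depth 27x, 500 individuals, and a relationship mix of 30/35/25/10% first to
fourth cousins whose length-weighted mean meioses is ~6.6 (between first-
and second-cousin parentage, matching the cohort the method was developed
for). The default genome for desk-scale tests is 4 chromosomes x 150 Mb at
1.25 cM/Mb, which preserves per-bp segment statistics; analyses that need
class separability (meiosis inference, end-to-end recovery) use the full
map.

What the generator deliberately does **not** emulate: read-level data (the
spike-in path abstracts the caller instead), recurrent mutation (planted
DNMs are unique singletons, so the regression's recurrence-removal bias
cannot be exercised), conversion tracts longer than one site (exome baits
make multi-site tracts rare), linkage between panel sites, population
structure in the SFS, and CpG-elevated mutability (the spectrum machinery
is tested on composition fixtures from `synth_reference()` instead).
Passing tests therefore demonstrate statistical correctness of the
estimation machinery under its stated model, not robustness to every
artifact of real exome data.

## Duplicate-pair generator

`generate_duplicates()` draws site frequencies on the same 0.01 grid the
replication curve is binned over (neutral 1/f weights at grid resolution).
This keeps simulate-bin-fit self-consistent: with continuous frequencies,
the many rare sites collapsing into the lowest bin would bias the fitted
rates — a discretization artifact of the curve representation, not of the
error model.

## Problem sizes used by the test-suite

Chosen as the package's own balance of Monte-Carlo resolution against a
desk-scale run: 10,000 pedigree replicates for the long-segment fraction;
2,000 training pedigrees per class and 400 held-out per class for the
classifier; 2,500 replicates per class for the inbreeding-coefficient
convergence; a 500-individual full-genome cohort with 1,000 bootstrap
replicates for end-to-end recovery; 176 duplicate pairs x 50,000 sites for
error-rate recovery. The complete suite runs in roughly seven minutes on
one CPU.

## Known limitations

* Crossover interference and obligate chiasma are not modeled; the >10 Mb
  tail is accordingly ~5-10% heavier than interference-aware simulation
  would give.
* Meiosis classes beyond the fourth cousin are not represented; individuals
  with more distant (or no) parental relatedness are absorbed by the
  fourth-cousin class or flagged uninformative.
* The intercept of the MAF-threshold regression retains the +~3.5%
  curvature bias described above; the singleton and intercept estimators
  should be read as bracketing values, as in the original analysis.
* Recurrent mutation and multi-site conversion tracts are not planted, so
  biases they cause in real data are quantified nowhere in this package.
* X-chromosome, indels and multi-nucleotide variants are out of scope.
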
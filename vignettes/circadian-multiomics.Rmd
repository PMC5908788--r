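---
title: "Circadian multi-omics analysis with circomics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian multi-omics analysis with circomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`circomics` implements a pipeline for diurnal-rhythm analysis of
multi-omics time courses of the kind produced by mouse-liver circadian
studies: each omics layer (transcription-factor DNA-binding activity
measured by a response-element pull-down, nuclear and whole-tissue
proteomes, phosphoproteome, ubiquitylome, transcriptome, cell-type
sub-proteomes) is a feature-by-timepoint matrix sampled every 3 h over
two consecutive daily cycles (16 samples, ZT0 to ZT45, where ZT is
Zeitgeber time -- hours since lights-on). The pipeline

1. normalizes (fraction-of-total, then per-cycle z-scores),
2. tests every feature for rhythmicity with a nonparametric
   JTK-family test,
3. groups the day into four 6-h time phases and selects
   phase-specific regulators,
4. nominates *dominant rhythmic transcription factors* (DR-TFs):
   TFs rhythmic in DNA-binding activity whose target genes are also
   enriched for rhythmicity, and
5. runs correlation, shortest-path and resampling analyses on
   user-supplied regulatory and protein-interaction networks.

A synthetic-data generator with complete ground truth accompanies
every stage so that power, calibration and recovery are testable.

## Normalization

**Fraction of total (FOT).** Each raw iBAQ column is divided by its
total over non-missing entries, making samples comparable. FOT is kept
as a plain fraction (no ppm scaling): downstream z-scoring is
scale-invariant, so only comparability matters. FOT is compositional;
with very few features, closure can induce artificial anti-correlation
between rows (visible in toy matrices, negligible at realistic feature
counts).

**Per-cycle z-scores.** Within each daily cycle, each feature row is
transformed to $z = (x - \mu)/\sigma$ with the cycle mean and the
*sample* (n-1) standard deviation -- the convention for 8 points per
cycle; the choice is recorded in the run manifest. A cycle in which a
feature is constant carries no rhythm information: its entries become
missing and the feature is flagged, rather than entering the rank test
as fabricated ties. Whether the two cycles should be scored jointly or
separately is ambiguous in common practice ("the mean of one cycle");
per-cycle is the default, and a joint mode is available by passing a
single covering interval to `cycle_spec()`.

## The rhythm test

The test is a from-scratch member of the JTK_CYCLE family. For each
admissible period $P$ and phase lag $\phi$, a reference template is the
rank vector of $\cos(2\pi(t-\phi)/P)$ at the sampled timepoints; the
data are compared with each template by Kendall concordance
$$S = \#\text{concordant} - \#\text{discordant}$$
over pairs untied in the reference.

* **Grid.** Periods are restricted to integer multiples of the
  sampling interval inside the configured range, so 20-28 h at 3-h
  sampling yields 21, 24 and 27 h; lags step by the sampling interval
  within one period. Templates with identical rank vectors are
  deduplicated, and the deduplicated count is the Bonferroni factor:
  treating amplitude and phase as free parameters is a search that the
  adjustment must pay for.
* **Exact null.** Under a uniformly random ordering of the data, the
  discordance count relative to a reference with tie groups
  $t_1,\dots,t_g$ is distributed as the inversion count of a uniform
  random multiset permutation. Its generating function is the Gaussian
  ($q$-)multinomial coefficient, computed exactly by convolving
  Gaussian binomials group by group (each intermediate is itself a
  Gaussian binomial with integer coefficients, so the computation is
  stable). P-values are two-sided tails of $S$. Beyond $n = 50$ a
  seeded permutation approximation takes over.
* **Ties and missingness.** Data-tied pairs are excluded from $S$ and
  from the tau denominator (tau-b style); the null keeps the
  reference-only tie pattern, which is conservative. If more than 25%
  of a feature's pairs are data-tied, a seeded permutation null
  replaces the exact one. Features with missing values are rescored
  against templates rebuilt on their observed timepoints, with the
  exact null recomputed for the reduced tie pattern. Constant features
  and features with fewer than 4 observations are carried through with
  $p = 1$.
* **Best template and adjustment.** Per feature the minimum raw $p$
  over the grid is taken and multiplied by the template count (capped
  at 1). Both $p_{raw}$ and $p_{adj}$ are reported; classification
  gates on $p_{adj} < \alpha$ strictly, with $\alpha = 0.1$ for
  proteome-type layers and $0.05$ for transcripts.
* **Tie-break and phase estimate.** At equal minimum $p$ the
  *positively* concordant template is preferred: a 24-h template and
  its antiphase partner have identical two-sided $p$ and identical
  $|\tau|$, and only the positively associated one's lag is a peak
  time. The reported `best_lag_h` is then projected onto the 24-h
  clock as the circular mean of the template's peak times inside the
  observation window -- an identity for 24-h templates, and the
  unbiased clock-time summary for 21/27-h templates whose peaks drift
  across the two cycles. Without both choices, phase recovery on
  planted cosines degrades from ~99% to ~75% within +-3 h.
* **Amplitude.** Half the difference between the mean of the values at
  the best template's top-quartile reference ranks and the mean at its
  bottom-quartile ranks. This estimator is non-canonical (the
  literature reports none for this test family) but monotone in the
  true amplitude for fixed noise.

Two-cycle courses are analysed as a single 48-h series with the
template wrapped at its period, matching the 16-column layout of
two-cycle studies.

## Time-phase machinery

The 24-h day is split at lights-on into TP1 = [ZT0,6), TP2 = [6,12),
TP3 = [12,18), TP4 = [18,24); daytime is ZT0-12. A feature is
*TP-specific* when its mean over one phase's samples (both cycles)
strictly exceeds `tp_fold` (default 2) times its mean over **each**
other phase separately. The "each phase separately" reading is the
stronger of the two readings of "more than twofold greater than the
rest"; it guarantees a unique phase per feature, and a pooled-rest mode
is available by flag. Phase means are computed on the FOT scale --
fold ratios are meaningless on zero-centred values; both the scale and
the phase boundaries are recorded in the manifest since neither is
universal. Peak times come from the rhythm table for rhythmic features
and from the cycle-averaged argmax otherwise; the day/night screen
selects features whose day/night mean ratio exceeds `day_night_fc`
(default 5, strict), with a zero minimum reported as infinite and
flagged rather than dropped.

## DR-TF nomination

"Controls the rhythmicity of its target genes" needs a concrete rule;
this package's is: a TF is a DR-TF iff (a) it is rhythmic in
DNA-binding activity at the proteome threshold, (b) at least `min_tg`
(default 3) of its network targets are measured in the transcriptome,
and (c) its measured targets are enriched for rhythmicity against the
transcriptome background by a one-sided hypergeometric test at
`enrich_alpha` (default 0.05). Both knobs are configurable and
manifest-recorded; no published threshold exists for this rule, so the
original study's DR-TF count is not a reproduction target. Edges are
labelled *activator* when the Pearson correlation between TF activity
and target transcript exceeds +0.5 (strict) and *repressor* below
-0.5, on z-scored profiles across all timepoints, pairwise-complete.

Ubiquitylation coupling is summarised as four percentages
(ubiquitylated fraction of rhythmic TFs, of non-rhythmic TFs, and of
each group's target-gene *union* -- a shared target counts once), and
tested by resampling same-size TF sets uniformly without replacement;
the empirical p uses the add-one estimator
$(1 + \#\{null \ge obs\})/(n_{iter}+1)$, which never reports zero.

## Network analyses

Shortest paths are unweighted breadth-first distances on the supplied
interaction graph; unreachable pairs are excluded from per-substrate
means rather than assigned a pseudo-distance that would dominate them.
"Pair tailed Student's t test" is read as a paired two-tailed t-test,
because every compared quantity is a per-entity pair (per substrate,
per mediator). The correlation-set comparison pairs by Mediator
subunit (each subunit's mean correlation over pathway TFs vs over all
TFs) so the paired test is well-defined. Each TF is linked to its
`mediator_k` (default 3) most-correlated Mediator subunits, ties on r
broken lexicographically. Set enrichment is a one-sided hypergeometric
tail with Benjamini-Hochberg correction across sets (configurable
off).

## The synthetic world

The generator's defaults are the stated study design: 16 samples at
3-h spacing over 48 h; 300 TFs of which 27% are rhythmic (the study
scale: 80 rhythmic of 297); 57.5% of rhythmic TFs dominant-rhythmic
(46 of 80); 10 target genes per TF; ubiquitylation rates 5%/2% for
rhythmic/other TFs and 8%/6% for their targets; signal-to-noise ratio
(cosine amplitude over Gaussian noise sd) 4, with noise sd 1 -- the
study states no noise model for binding-activity measurements, so SNR
is a free parameter and recovery claims hold at the stated SNRs only.

Planted rhythms are cosines,
$x(t) = b + A\cos(2\pi(t-\phi)/24) + \varepsilon$: the test family's
reference is a cosine, so power and phase-recovery results are
interpretable. Rhythmic acrophases cycle over the four phase midpoints
(ZT 1.5, 7.5, 13.5, 19.5) so every phase receives planted
phase-specific TFs. Target genes share their TF's acrophase (activator
edges) or sit 12 h opposite (repressor edges) with independent noise;
coupling is correlational, not kinetic, because the DR-TF logic itself
is correlational.

**Why phase-specific TFs are bumps, not cosines.** A nonnegative pure
cosine can never pass the strict twofold rule: its peak-phase mean is
$b + 0.924A$ and must exceed $2b$, while its trough-phase mean
$b - 0.924A$ must stay nonnegative -- the two requirements meet only
at equality. Planted phase-specific TFs therefore use a von-Mises-type
bump $b' + H e^{\kappa(\cos(2\pi(t-\phi)/24)-1)}$ with $\kappa = 4$,
height $H = 2 \cdot snr \cdot \sigma$ (the peak-to-trough excursion a
cosine of amplitude $snr\cdot\sigma$ would have) and baseline
$b' = 0.1H$, clipped at zero. These constants follow from the
inequality above plus the requirement that phase-mean contrasts clear
the twofold threshold by several noise standard errors at the stated
SNR; they were fixed a priori, not tuned.

**What the generator does not emulate.** Missingness is uniform at a
configurable rate -- there is no intensity-dependent (MNAR) censoring
as in real MS data; no batch or run-order effects; waveforms are
symmetric (no sawtooth or pulse shapes); the regulatory network is
block-structured (disjoint target sets per TF) and the interaction
graph Erdos-Renyi, both far simpler than CellNet or STRING topology.
A green recovery test therefore establishes correctness of the
implemented rules under the stated model, not robustness to real-data
pathologies.

## Numerical choices and degenerate inputs

* Template ranks are computed after rounding the cosine to 9 decimals,
  so analytically tied phases are tied in floating point.
* The exact-null convolution is normalised per merge step, keeping all
  magnitudes near 1; tail p-values are exact to double precision at
  n = 16.
* Strictness conventions: `p_adj < alpha`, `fold` ratios `>`,
  correlation thresholds `>` / `<`, day/night fold change `>` -- all
  boundaries exclude.
* All-zero FOT columns, duplicate feature ids, malformed ZT headers,
  non-numeric cells and out-of-range signs are hard errors naming the
  offending row/column; constant features, short series and empty
  denominators are carried through flagged rather than silently
  dropped.
* Determinism: every stochastic step (generator, resampling,
  permutation fallback) is driven by the run seed; rerunning the
  pipeline with identical inputs, configuration and seed reproduces
  every output byte for byte.

## Known limitations

* Periods are limited to multiples of the sampling interval; 20-28 h
  at 3-h sampling probes only 21/24/27 h. Finer period resolution
  would need interpolated templates, which this test family avoids.
* Bonferroni over templates is conservative (templates are strongly
  correlated), so realised type-I error runs well below nominal and
  power at low SNR is sacrificed for error control.
* Cross-layer joins are by exact gene-symbol match; isoforms and
  site-level features must be collapsed to symbols upstream, and no
  harmonisation beyond exact matching is attempted.
* The hypergeometric DR-TF rule treats targets as exchangeable; it
  does not model shared targets between TFs or network uncertainty.
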
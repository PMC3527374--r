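---
title: "Modelling the functional operating range of denitrifier communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the functional operating range of denitrifier communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denitrange)
```

## The scientific problem

The *functional operating range* of a microbial community is the span of
environmental conditions over which it maintains a measured function. This
package implements that analysis for soil denitrifiers: potential
denitrification (anaerobic N2O production with acetylene blocking N2O
reduction) is assayed in soil-slurry microcosms along a temperature gradient
and a NaCl gradient, response curves are fitted per field replicate, and the
curve parameters are compared across communities and linked to the diversity
and composition of the denitrifier guild as seen through *nosZ* clone
libraries.

## Rate estimation

Each flask yields an N2O accumulation time series (default: every 0.5 h over
3 h). Headspace amounts are first corrected for the fraction dissolved in the
slurry,

$$A_\mathrm{total} = A_\mathrm{headspace}\left(1 + \beta(T)\,
  \frac{V_\mathrm{liquid}}{V_\mathrm{headspace}}\right),$$

with $\beta(T)$ the dimensionless Bunsen solubility coefficient of N2O in
water, linearly interpolated in a 0–60 °C reference table (`n2o_bunsen()`).
No extrapolation is allowed outside the table. Salinity effects on
solubility are ignored because the salt series is incubated at a single
temperature (30 °C). The rate is then the ordinary least-squares slope of
amount against time (`fit_linear_rate()`); because the correction factor is
constant in time, correcting before or after the regression gives identical
rates (a property the test suite asserts). Negative fitted slopes are floored
at zero — production rates are physically non-negative, and inhibition is
expressed through the response models, not through negative rates.

## Temperature response: the Gaussian model

Rates along the temperature gradient are fitted with

$$v(T) = v_\max \exp\!\left(-\frac{(T - T_m)^2}{2 w^2}\right),$$

where $v_\max$ is the maximum rate, attained at the optimum temperature
$T_m$, and $w$ (°C) measures the width of the curve; $2\sqrt{2\ln 2}\,w
\approx 2.355\,w$ is the full width at half maximum (`fwhm()`). Fitting is
nonlinear least squares (Levenberg–Marquardt) with multi-start
initialisation: $T_m$ starts at the argmax of the observed rates, $v_\max$
at the observed maximum, and $w$ at a second-moment estimate of the spread,
with additional starts spread over the observed temperature range. The width
is reported as $|w|$ (the model is even in $w$). Goodness of fit is the
adjusted $r^2$ with $p = 3$ parameters.

## Salt response: the power model

Rates along the NaCl gradient are fitted with

$$v(c) = k\,c^{-1/2} - a,$$

estimated — exactly as the model is defined — by linear regression of $v$ on
$c^{-1/2}$, with slope $k$ and intercept $-a$. Two derived thresholds
summarise the salt operating range: activity is completely inhibited at
$\mathrm{SA0} = (k/a)^2$ and begins to fall below the uninhibited rate $v_0$
at $\mathrm{SAI} = \left[k/(v_0+a)\right]^2$ (% w/v). Three choices deserve
comment:

* $c = 0$ is undefined under the model and is excluded from the regression;
  the uninhibited rate $v_0$ is taken as the observed rate at $c = 0$ (mean
  of replicate observations, or an explicit override). How the original
  analysis obtained $v_0$ is not documented; using the $c=0$ observation is
  the simplest estimator and keeps SAI a pure function of observables.
* Observations whose measured rate is zero are also excluded: under the
  clamped model every concentration beyond SA0 produces a zero rate that
  lies off the $c^{-1/2}$ line by construction, so including such points
  would bias $k$ and $a$ toward shallower inhibition.
* A non-positive fitted $k$ or $a$ means the data carry no inhibition
  signal; the fit is flagged and SAI/SA0 are undefined rather than reported
  as negative concentrations.

Curves are normalized to percent of the maximum rate per community replicate
(`normalize_rates()`); normalization rescales $v_\max$, $k$, $a$ and $v_0$ by
a common factor and therefore leaves $T_m$, $w$, SAI and SA0 unchanged, which
the tests verify by refitting normalized curves. Fits are done on raw rates
first, normalization applied afterwards for display and comparison.

## Comparing communities

Operating-range parameters ($T_m$, $w$, SAI, SA0) are compared across
communities by one-way ANOVA followed by Tukey's HSD at $\alpha = 0.1$
(configurable), with a compact letter display computed by the
insert-and-absorb algorithm: communities sharing a letter do not differ at
$\alpha$. Tukey p-values come from the studentized-range distribution
(`stats::TukeyHSD`).

## From clone libraries to genotypes: in-silico RFLP

Clone sequences are digested in silico with AluI (site AGCT, blunt cut
between G and C; any enzyme can be specified as site + cut offset).
Coordinates are 0-based half-open internally; overlapping site occurrences
are handled, and any non-ACGT character conservatively breaks a match.
Fragment lengths always sum to the sequence length.

Scoring emulates a 3% high-resolution agarose gel with two parameters:
`min_detectable` (default 50 bp) drops fragments below the detection limit,
and `resolution` (default 0.05) merges fragments whose lengths differ by at
most 5% of their mean into one band. Merging is performed on the pooled set
of fragment lengths so the same physical band is scored identically in every
profile, and each band is anchored at its smallest member so that bands stay
no wider than the gel resolution (transitive chaining of many close lengths
would otherwise collapse the ladder). Both parameters are exposed because no
numeric resolution is documented for the physical gel. Profiles are compared
as sorted multisets of band lengths — a gel does not preserve fragment
order — and clones with identical banded profiles form one RFLP group.
Shared and unique groups across communities are summarised as Venn region
counts on replicate-pooled presence.

## Diversity metrics

Richness and diversity are computed per replicate library and per
replicate-pooled community:

* **Chao1**, bias-corrected form $S_\mathrm{obs} + f_1(f_1-1)/(2(f_2+1))$,
  which is well defined when no doubletons exist; the 95% CI uses Chao's
  variance with the log-normal transformation on $T = \hat S - S_\mathrm{obs}$,
  so the lower bound never falls below the observed richness.
* **Shannon $H'$** with natural logarithm; normal-approximation CI with
  variance $(\sum p_i \ln^2 p_i - H'^2)/N + (S-1)/(2N^2)$.
* **Faith's PD**: the sum of branch lengths spanning a community's genotypes
  in the phylogeny. The default counts every branch leading to at least one
  present tip, i.e. the spanning subtree is rooted at the tree root (the
  classic formulation and the convention of established implementations);
  `include_root = FALSE` restricts to branches below the MRCA of the present
  set.
* **NRI / NTI**: standardized effect sizes of mean pairwise distance and
  mean nearest-taxon distance, $z = -(\mathrm{obs} - \bar x_\mathrm{null})/
  s_\mathrm{null}$, so positive values indicate phylogenetic clustering
  (environmental filtering) and negative values overdispersion. The null
  model draws richness-matched random tip sets from the tree's tip pool
  (999 draws by default, seedable); an exhaustive mode enumerates every
  subset on small trees and anchors the Monte-Carlo implementation in the
  tests. When the null has zero variance (e.g. the community spans the whole
  pool) the z-score is reported as 0 with a degeneracy flag. Two-sided
  p-values come from the null rank with the +1 correction.

## Community composition

* **Unweighted UniFrac** between two tip sets: branch length leading
  exclusively to one set's tips divided by branch length leading to either,
  a presence/absence measure in [0, 1].
* **AMOVA** partitions squared-distance variance among and within groups,
  reporting variance components, percent variation among groups, and
  $\Phi_{ST}$ with a label-permutation p-value. In the pipeline the AMOVA
  distance between clones is haplotype identity (0 within an RFLP group, 1
  between groups) in a one-level design permuting clones among communities;
  the distance choice is configurable because the original is undocumented.
* **NMDS** minimises Kruskal stress-1, delegating to `vegan::metaMDS`
  (monoMDS engine, no autotransform) with up to 20 random starts and
  Procrustes-based convergence — the same machinery the field uses. Stress
  is reported both as a fraction and ×100. `kruskal_stress()` recomputes the
  stress of any configuration by isotonic regression as an independent
  check.
* **Vector fitting** regresses a variable on the centered ordination
  coordinates; the normalized coefficient vector is the arrow, its $r^2$ the
  strength, significance by permuting the variable (exact enumeration
  available for small n).
* **Mantel test**: Pearson correlation over unique off-diagonal pairs,
  one-sided (greater) permutation test, +1 correction; exact mode for small
  n. One-sided greater is appropriate because the hypothesis is a positive
  association between community dissimilarity and metric dissimilarity.

All permutation engines take an explicit integer seed and restore the
caller's RNG state, so p-values are reproducible and p > 0 always.

## The synthetic-data generator

The generator produces ground-truth experiments with the statistical
structure the analysis assumes, at the reference design: 4 communities × 3
field replicates, temperatures {2, 10, 20, 30, 37, 45, 53, 60} °C, NaCl {0,
0.5, 0.75, 1, 1.5, 2, 3, 4} % w/v incubated at 30 °C, 7 sampling times over
3 h, ~100 clones per library, 708-bp marker sequences. Default true
parameters place the optimum temperature between 32.7 and 35.6 °C, widths
between 10.4 and 12.4 °C, SAI between 0.25 and 0.50% and SA0 between 2.4 and
5.9% w/v, with one community (J) carrying both the broadest temperature
width and the largest complete-inhibition threshold — the
insurance-hypothesis pattern the comparison stage must resolve. Maximum
rates rise from community A to J (60 to 140 rate units); the uninhibited
salt rate defaults to each community's Gaussian rate at 30 °C, making the
two gradients mutually consistent.

Gas curves are linear in time with i.i.d. Gaussian noise of sd
`noise_sd * v_max` (default 5%) added to the amounts and floored at zero.
The within-replicate noise structure of the real assay is unknown; Gaussian
noise on amounts is a modelling convenience, not an empirical claim. With
`headspace = TRUE` (the pipeline default) the produced amounts are
partitioned between headspace and liquid with the same Bunsen coefficients
the rates stage uses, so synthetic data exercise the correction path
end-to-end and noiseless series recover the true rates to machine precision.

Phylogenies are Kingman-coalescent genealogies (`ape::rcoal`): seedable,
ultrametric, with realistic clade structure for the NRI/NTI tests; optional
lognormal branch-length jitter breaks the clock. Communities draw their
genotype memberships from a shared core (controlled by `overlap`: 1 =
identical memberships, 0 = disjoint) plus community-unique genotypes;
abundances are lognormal with shape `evenness_sigma` (0 = uniform; large
values reproduce dominance by a few genotypes, as in the least-even
reference community), and each replicate library is a multinomial draw.
Sequences evolve from a random root along the tree under Jukes–Cantor with
no indels (`phangorn::simSeq`), so AluI profiles differ only through
substitutions creating or destroying sites — exactly the signal the RFLP
stage must detect. The default rate (0.15 substitutions/site per unit branch
length) yields ~25% mean pairwise divergence across the pool, comparable to
marker-gene clone libraries.

**What the generator does not emulate.** Coalescent genealogies concentrate
divergence deep in the tree: terminal branches are $O(1/n^2)$, so sister
tips are often identical at finite sequence length and the in-silico RFLP
resolves clades rather than individual tips (a 95-tip pool yields roughly
19 distinct AluI profiles at the default rate) — much as a physical gel
groups close relatives. There is no PCR bias, chimera formation, indel
evolution, or abundance-weighted UniFrac input. Passing tests therefore
demonstrate correctness of the estimators and their couplings under the
assumed statistical structure, not robustness to those artefacts of real
libraries.

## Numerical choices and degenerate inputs

* Gaussian fit: up to 9 starts; an error lists the starts tried if none
  converges. Perfect (zero-residual) fits report adjusted $r^2 = 1$.
* Linear rate fit with zero amount variance reports $r^2 = 1$ when residuals
  vanish (a constant series is fitted exactly by slope 0).
* All-zero curves cannot be normalized (error), all-zero count vectors have
  no diversity (error), singleton communities have no MPD/MNTD (error).
* Letter display: groups are ordered by first occurrence; one letter is
  assigned per maximal mutually-non-significant block surviving
  insert-and-absorb.
* Problem sizes in the tests and the acceptance script are those of the
  reference design (8 + 8 gradient points, 4 × 3 replicates, 100-clone
  libraries); parameter-recovery summaries use 25 seeded experiment
  replicates × 4 communities, NRI/NTI Monte-Carlo checks use 9,999 null
  draws against exhaustive enumeration on trees of at most 8 tips.

## Known limitations

Only one-level AMOVA is provided (no hierarchical designs); UniFrac is
unweighted only; no alternative temperature models (Arrhenius,
cardinal-temperature) or model selection; rarefaction and coverage
estimators beyond Chao1 are out of scope. The reference analysis described
its UniFrac matrix ambiguously as "(Bray-Curtis)"; this implementation
ordinates the UniFrac distances directly rather than guessing a Bray–Curtis
recomputation.
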
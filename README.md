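# denitrange

Functional operating range of soil denitrifier communities: estimate
potential denitrification rates from N2O accumulation assays along
temperature and salt gradients, fit the response models that define the
operating range, and relate the fitted range to the diversity and
composition of the denitrifier guild seen through *nosZ* clone libraries.

The package is aimed at soil microbial ecologists who run potential-activity
microcosm assays across environmental gradients and genotype the underlying
guild by cloning/RFLP or sequencing. It covers the full chain: a seedable
synthetic-data generator (gas curves, coalescent phylogenies, clone
libraries, sequence evolution), rate estimation with the dissolved-gas
correction, response-model fitting with community comparison, in-silico
restriction digestion and RFLP grouping, richness/diversity and phylogenetic
community metrics, and phylogeny-based composition analysis.

## The models

Temperature response (Gaussian):

    v(T) = v_max · exp(−(T − T_m)² / (2 w²))

`v_max` is the maximum rate at the optimum temperature `T_m`; `w` (°C)
measures the curve width, and `2.355·w` is the full width at half maximum
(FWHM) — the temperature operating range.

Salt inhibition (power model, fitted as a line in `c^−0.5`):

    v(c) = k·c^−0.5 − a

from which two thresholds follow: activity ceases at `SA0 = (k/a)²` and
begins to fall below the uninhibited rate `v0` at `SAI = (k/(v0+a))²`
(% w/v NaCl). Parameters are fitted per field replicate and compared across
communities by ANOVA + Tukey HSD at P < 0.1 with a compact letter display.

Diversity and composition: bias-corrected Chao1 and Shannon H′ with 95% CIs,
Faith's PD, NRI/NTI against a seedable tip-pool null, unweighted UniFrac,
one-level AMOVA with Φ_ST, NMDS (Kruskal stress-1, 20 random starts),
ordination vector fitting, Mantel tests, and pairwise metric correlations.

## Worked example

```r
library(denitrange)

temps <- c(2, 10, 20, 30, 37, 45, 53, 60)
set.seed(42)
rates <- gaussian_rate(temps, v_max = 120, t_m = 34, w = 11.5) + rnorm(8, 0, 4)
fit <- fit_gaussian(temps, rates)
sprintf("t_m=%.2f w=%.2f fwhm=%.2f adjr2=%.3f", fit$t_m, fit$w, fit$fwhm, fit$adj_r_squared)
#> "t_m=34.06 w=11.68 fwhm=27.51 adjr2=0.992"

salts <- c(0, 0.5, 0.75, 1, 1.5, 2, 3, 4)
sfit <- fit_power(salts, power_rate(salts, k = 60, a = 25, v0 = 118))
sprintf("k=%.1f a=%.1f SAI=%.3f SA0=%.2f", sfit$k, sfit$a, sfit$sai, sfit$sa0)
#> "k=60.0 a=25.0 SAI=0.176 SA0=5.76"
```

The first fit says this community's denitrification peaks at 34.1 °C and
stays above half its maximum over a 27.5 °C-wide window; the second says
salt begins to inhibit activity at 0.18% NaCl and shuts it down completely
at 5.8%.

The full pipeline — simulate, rates, fit, RFLP, diversity, composition — runs
from one configuration:

```r
res <- run_pipeline(default_config(seed = 1, out_dir = "out"))
res$fits$comparison_table      # Table of t_m, w, SAI, SA0 mean(sd) + letters
res$diversity                  # Chao1/H'/PD/NRI/NTI per replicate & community
res$compare$amova$percent_among
res$compare$mantel$r
```

A thin command-line front end with subcommands (`simulate`, `rates`,
`fit-temperature`, `fit-salt`, `rflp`, `diversity`, `compare`, `run-all`)
is installed at `inst/cli/denitrange`; every flag mirrors a key of the flat
key-value config format read by `read_config()`.

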
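---
title: "levelscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{levelscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levelscan)
```

levelscan analyzes experiments that ask which genes set the *level* of a
protein of interest: pooled dual-guide CRISPRi screens read out by FACS
sorting of a fluorescent reporter, cross-screen fixed-effects meta-analysis,
pulse-SILAC protein turnover, and an RNA-seq normalization/filter chain with
splice-junction and polyadenylation event classification. Every analysis
stage ships with a matched synthetic-data generator that returns its ground
truth, so recovery is checkable end to end.

# Sorting-screen model and scoring

## Generative model

`simulate_sorting_screen()` models a pooled screen in which each gene is
covered by several dual-guide cassettes (two guides against the same gene on
one construct) plus non-targeting (NT) control cassettes. Reporter
fluorescence per cell is Normal(effect, 1) in units of the within-cell
reporter SD, so `effect_size_sd_units` is directly interpretable: a -1 hit
shifts a cell population one SD down. Cells are pooled, the lowest and
highest `sort_fraction` (default 25%) are gated on the *pooled* fluorescence
distribution, and sequencing reads are emitted per bin by multinomial
sampling of the sorted cells. A fraction `recombination_rate` of read pairs
carries two independently drawn cassettes, emulating lentiviral
template-switching; these are the reads the recombination filter must
remove. Cassette abundances are lognormal (sdlog 0.25) around
`cells_per_guide`.

The closed-form companion `expected_bin_ratio(effect, sort_fraction)` gives
the expected high/low representation ratio of a shifted cassette from Normal
tail masses; the test suite holds the simulator to it.

What the generator does *not* model: guide-level efficacy variation, growth
effects between infection and sort, PCR jackpotting beyond the lognormal
abundance spread, or sorting impurity. These widen real null distributions;
the scoring stack absorbs such overdispersion through its empirical
mean-variance trend rather than through the generator.

## Scoring

1. `filter_recombined_pairs()` keeps a read iff both guides map to the same
   gene (NT-NT pairs are kept as controls) and tallies the rest.
2. `aggregate_counts()` tallies reads per cassette and bin;
   `filter_low_count_guides()` drops cassettes below a mean count of 10;
   `normalize_counts()` applies median-ratio size factors (geometric-mean
   reference over all-positive rows, total-count fallback below 100 usable
   rows).
3. `guide_nb_test()` tests each cassette's high-bin count against a negative
   binomial whose mean is the (floored) low-bin count and whose variance
   follows a trend `var = mu + k * mu^b` fitted across all cassettes on
   log(var - mean) vs log(mean). The fit uses Tukey's resistant line
   (`stats::line`) rather than least squares: planted hits are extreme
   points in exactly the region that an OLS fit lets dominate, and a
   resistant fit keeps the null trend honest without having to know which
   cassettes are hits. With too few usable points (or a non-positive k) the
   test falls back to Poisson.
4. `gene_rra()` aggregates guides per gene by robust rank aggregation:
   cassettes are ranked by directional p (percentile rank `(rank - 0.5)/N`,
   ties broken by cassette id), guides with p below `alpha = 0.25` are
   selected, and the gene score is the minimum Beta order-statistic tail
   probability `rho = min_j pbeta(r_(j), j, m - j + 1)`. Significance comes
   from a permutation null that draws each gene's ranks uniformly and
   selects them below the *empirical* fraction of cassettes passing the
   alpha cut, keeping observed and null selection rules identical. The null
   is shared across genes with the same guide count, which makes the
   permutation affordable; the +1-corrected p has resolution `1/(n_perm+1)`,
   so the default `n_perm = 1000` supports BH calls at q < 0.05 for
   hit fractions around 5%. NT cassettes participate in the ranking but are
   excluded from gene aggregation.
5. `screen_summary()` combines the two directions per gene by doubling the
   smaller directional p (capped at 1).

At the package's reference scale (500 genes x 4 guides + 100 NT cassettes,
500x depth, 10% recombination, -1 SD hits) the chain recovers planted hits
with recall 1.0 and no false positives at `fdr < 0.05`; one run takes under
10 s.

# Fixed-effects meta-analysis

Screens report effects on different scales, so `harmonize()` maps each
summary to a standardized beta/SE pair: p-values are truncated to
`[1e-300, 1 - 1e-16]` (conservative at both ends; the z computation uses the
upper-tail `qnorm` parameterization so it stays finite at the floor),
`z = sign(effect) * qnorm(p/2, lower.tail = FALSE)`, effects are optionally
z-scored within the screen, and `se = |beta/z|`. A zero effect yields an
infinite-SE sentinel that drops out of pooling with zero weight.

`fixed_effect_pool()` is the textbook inverse-variance estimator
(`w = 1/se^2`, pooled beta `sum(w b)/sum(w)`, pooled SE `sum(w)^(-1/2)`)
with Cochran's Q, `df = k - 1`, and `I2 = max(0, (Q - df)/Q)`.
`meta_all_combinations()` runs every subset of screens of size >= 2, and
`classify_novelty()` flags genes significant after FDR adjustment of the
meta-analysis but in none of the constituent screens, with an optional
effect filter (`|effect - mean(effect)| >= 1`) for designated screens whose
effects are log-fold-changes. Under a two-screen global null the pooled p is
uniform (type-I 0.048-0.053 at 0.05) and Q follows chi-squared with one
degree of freedom; with three screens at ~40% individual power the pooled
analysis detects essentially all shared hits at under 10% empirical FDR.

`hypergeom_enrichment()` adds term enrichment with a permutation FDR: random
hit sets of the observed size are redrawn from the universe `n_perm` times
and the FDR per term is the mean ratio of null to observed terms at or below
its p.

# Pulse-SILAC turnover

After a switch to heavy media, steady-state turnover gives a heavy/light
ratio `R = 2^(t_s/T) - 1` at labeling time `t_s`, inverted by
`peptide_half_life()` as `T = t_s * ln 2 / ln(1 + R)`.
`filter_peptides()` removes contaminant-flagged rows, rows with total
intensity below 1000, and ratios outside [0.01, 100]; all three cuts are
strict inequalities (boundaries kept), and a row failing several rules is
tallied once, in the order contaminant, intensity, ratio.
`protein_half_life()` collapses duplicate peptide sequences (charge states,
repeated identifications) to their median and aggregates unique peptides by
the harmonic mean, the natural average for rate-derived quantities.
`contrast_half_life()` and `contrast_abundance()` run Welch t-tests across
replicates on the log2 scale with volcano thresholds (0.5, 0.05) and
(1, 0.05) respectively.

`simulate_silac_peptides()` perturbs true ratios with mean-one lognormal
noise of configurable CV and injects contaminants, out-of-range ratios, and
sub-floor intensities at configurable rates. At CV 0 the round trip is exact
to machine precision; at CV 20% with 3-8 peptides per protein the median
absolute relative half-life error is ~4%. The generator assumes steady
state, no recycling of heavy label, and noise independent across peptides --
real data violate all three mildly, which inflates errors beyond the
simulated regime.

# Transcript-level filters

`cpm_pedestal_log2()` computes `log2(count * 1e6 / colsum + 2)`; the
pedestal of 2 stabilizes low counts. `cyclic_loess_normalize()` wraps
limma's pairwise cyclic loess. Loess removes between-sample distortions that
are *smooth at its bandwidth*: a global shift or a slow intensity-dependent
bias is removed nearly completely (>= 10-fold reduction in the test
fixtures), while distortions oscillating faster than the span window cannot
be, which is a property of the method and not of this implementation.

`noise_filter()` computes, per group, gene means and CVs on the linearized
scale, fits a lowess CV~mean trend, and sets the group's threshold where the
trend crosses a ceiling of `median(cv) + 2 * mad(cv)`; a gene is removed iff
its mean falls below the threshold in *every* group, so a gene expressed
well in any condition survives.

`differential_expression()` defaults to limma's moderated t. A per-gene
Welch test is available (`method = "welch"`) and is well calibrated at 6+6
replicates, but at the 3-4 replicates typical of these designs it has too
little power against 4-fold changes (~38% recovery in the package's own
simulations versus ~97% for the moderated test), and mild conservatism
(type-I ~0.037 at 0.05). Variance moderation is the standard remedy, so it
is the default rather than an option.

`classify_junctions()` implements the cryptic-splicing rule on
percent-spliced-in values: `cryptic_gain` when the between-group dPSI
exceeds 0.10 and the junction is present (PSI > 0.01) in fewer than 5% of
control samples; `cryptic_loss` when dPSI < -0.10 with presence above 10%;
junctions passing only the dPSI cut are `significant_noncryptic`.
`filter_polya_events()` classifies polyadenylation events by compositional
fold change with an inclusive cFC boundary (>= 0.25) and an exclusive FDR
boundary (< 0.05).

# Pipeline and reproducibility

`run_pipeline()` takes a structured configuration (list or YAML) with a
global seed, an output directory, and named stages; the whole configuration
is schema-validated -- unknown keys rejected, input files checked -- before
any computation starts. Stage `i` derives its seed as
`(seed * 31 + i) mod (2^31 - 1)`, decoupling stages while keeping every
derived seed a valid integer. Stage parameters may reference earlier outputs
as `"@stage.table"`. Each run writes its tables as TSV plus a
`manifest.json` with parameters, per-stage seeds, and md5 checksums;
identical configurations reproduce identical manifests. A thin command-line
wrapper is installed at `system.file("cli", "levelscan", package =
"levelscan")`.

# Numerical and testing choices

* All simulator randomness flows through an internal `with_seed()` that
  restores the caller's RNG state, so library calls never perturb user code.
* Permutation p-values carry the +1 correction and are therefore never 0.
* The test suite checks implementations against *independent* oracles:
  brute-force step-up BH, direct negative-binomial pmf summation, grid
  enumeration of the RRA null for two-guide genes, per-record re-statements
  of every filter rule, and `metafor::rma(method = "FE")` for the pooling
  identities.
* Genes sharing a permutation null have exchangeable but dependent
  p-values, and genes with no selected guide sit at an atom at p = 1, so
  null calibration is asserted as tail-fraction bands rather than a KS test
  against the continuous uniform.

Problem sizes used in tests and in `scripts/acceptance.R` (500-gene
screens, 5000-gene null meta, 500-protein turnover panels) are the
package's own reference scales, chosen to finish in seconds to minutes on
one CPU while leaving narrow Monte-Carlo bands around the asserted
quantities.

# Limitations

The generators are deliberately minimal: they produce the failure modes the
filters are built for (recombined reads, contaminants, out-of-range ratios,
noise-biased genes, near-absent control junctions) and nothing else. The
screen model has no growth-phenotype confounding; the meta model draws
independent Gaussian effects rather than screen-specific systematic biases;
the turnover model ignores label recycling. Conclusions about robustness to
artifacts outside this list do not follow from the test suite.
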
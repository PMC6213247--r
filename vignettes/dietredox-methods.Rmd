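---
title: "Methods: redox-proteomics and lipid-profile analysis of diet-intervention cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: redox-proteomics and lipid-profile analysis of diet-intervention cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietredox)
```

# The study design this package models

`dietredox` implements the computational analysis of a three-arm rodent diet
intervention: a standard-chow control (STD), a high-fat high-sucrose arm
(HFHS), and an HFHS arm supplemented with marine omega-3 fatty acids, EPA and
DHA in a 1:1 ratio (HFHS+w3), with n = 9 animals per group. The readouts are

* liver fatty-acid composition by GC-FID, expressed as percentages of total
  fatty acids;
* protein carbonylation — an irreversible oxidative post-translational
  modification — measured on 1-D and 2-D gels by FTSC fluorescence
  (carbonyl-specific channel) over Coomassie optical density (protein-amount
  channel);
* biometric, plasma and antioxidant-enzyme measurements;
* descriptive gene-ontology and interaction-network summaries of the
  identified carbonylated proteins.

Raw per-animal data for such studies are typically not deposited; what is
published are group means and standard deviations. The package therefore
couples every analysis stage to a synthetic-cohort generator parameterized by
those printed summaries, so the full pipeline runs, and is tested, without
any external download.

# Derived indexes

## Fatty-acid profile quantities

A profile maps shorthand acid names (`16:1ω7`, `22:6n-3`, ...) to percentages
of total fatty acids; `parse_fa_name()` normalizes the spelling dialects that
appear in print (`ω3`, `ω-3`, `ω − 3`, `n-3`, `w3`). Class sums follow the
standard conventions: SAT (no double bonds), MUFA (exactly one), PUFA (two or
more), with the ω-3/ω-6 rows counting PUFAs of those families only — this is
the convention that reproduces the published class rows from the published
acid rows. Desaturase activity is estimated as the product/substrate
percentage ratio: SCD-16 = 16:1n-7/16:0, SCD-18 = 18:1n-9/18:0, Δ4D =
22:6n-3/22:5n-3, Δ5D = 20:4n-6/20:3n-6, Δ6D = 20:3n-6/18:2n-6 (and the
18:3n-6/18:2n-6 variant), Δ5/6D = 20:5n-3/18:3n-3, plus the EPA/DHA ratio.
A zero (or absent) substrate yields an *undefined* index (`NA`), never an
error, so per-sample panels stay computable.

**Mean of ratios vs ratio of means.** Ratio-valued rows (desaturase panel,
GSSG/GSH, AST/ALT) are computed per animal and then averaged in the pipeline
— the convention the published tables themselves follow, visible because
several printed panel cells differ from the ratio of the printed group means
(e.g. SCD-18 in the control arm prints 0.87 while 8.24/9.81 = 0.84).
`reproduce_printed()` therefore recomputes the panel in ratio-of-means mode
and *reports* each cell's agreement instead of asserting it; the cells that
agree at two decimals (SCD-16 in all groups, Δ6D in the two control arms)
are the ones the acceptance tests pin down.

**Rounding.** Printed-precision comparisons round half away from zero
(`round_half_up()`), matching how the tables were typeset; base R's
round-half-even would move 0.065 to 0.06.

**Known unknown.** The composition table also prints "% EPA PUFAs" and
"% DHA PUFAs" rows (0.18/0.14/0.46 and 2.59/2.95/4.61) that match no ratio
of other printed cells we could identify; their defining computation is not
stated, so they are excluded from reproduction.

## Carbonylation indexes

The carbonylation index of a spot, band or lane is its FTSC intensity
divided by its Coomassie intensity — carbonyl load normalized for protein
amount. Within a gel and channel, `ppm_normalize()` expresses spot
intensities as parts per million of the total integrated optical density,
removing loading and exposure differences between gels.

For the per-spot index the package defaults to the **raw intensity ratio**
and offers ppm-mode as an option. The reason is arithmetic, not taste: the
ratio of two ppm values equals the raw ratio times the gel's (total
Coomassie)/(total FTSC) factor, and the Coomassie-weighted mean of ppm-mode
indexes is identically 1 on every gel. Ppm-mode indexes are therefore
*relative to the gel's overall carbonylation load*: no configured set of
per-spot index targets can be recovered from them, and gels with globally
higher carbonylation would have their spot indexes deflated. The raw ratio
is also what the index definition states literally. Both modes are invariant
under simultaneous rescaling of the two channels.

**Detection limit.** Some intensely fluorescent spots sit below the
Coomassie stain's detection range (about 100 ng of protein); their index is
undefined. Since nanograms are not observable from densitometry tables, the
limit is expressed as a configurable raw Coomassie intensity threshold
(default 1000 arbitrary units in the generator's scale). Undefined indexes
propagate to statistics as missing values, never as zeros — zeros would
drag group means toward the origin and manufacture spurious significance.

## Biometric indexes

Adiposity index = abdominal (perigonadal) fat × 100 / body weight;
hepatosomatic index = liver weight × 100 / body weight. Both are
dimensionless percentages, homogeneous of degree zero in the masses. The
perigonadal depot is used as "total abdominal fat" because it is the only
fat mass printed and it reproduces both printed adiposity cells.

# The comparison engine

`group_compare(value ~ diet_group, data)` runs the route used for every
variable:

1. **Assumption checks** (`check_assumptions()`): Shapiro–Wilk normality per
   group and a median-centered Levene (Brown–Forsythe) homogeneity test,
   each at α = 0.05. Any rejection routes the variable to the nonparametric
   branch. The study names neither specific test, so both are the package's
   choices and the routing level is a parameter. Groups with fewer than
   three values or zero variance make normality untestable: nonparametric
   with a warning.
2. **Omnibus**: one-way ANOVA (parametric) or Kruskal–Wallis (nonparametric),
   missing values dropped.
3. **Post-hoc**: Fisher's least significant difference — pairwise t
   statistics on the full model's pooled mean-square error and residual
   degrees of freedom, two-sided, *unadjusted* (that is LSD's definition).
   With two groups LSD collapses exactly to the pooled-variance t-test,
   which the tests verify to 1e-10. On the nonparametric branch the
   pairwise step is an unadjusted Mann–Whitney test with midranks and
   continuity correction; the published methods are silent on this step, so
   the choice is documented rather than attributed.
4. **Annotation**: stars use strict thresholds (* p < 0.05, ** p < 0.01; a p
   of exactly 0.05 earns nothing) against a reference group (default STD);
   arrows mark significant pairwise changes only and always agree with the
   sign of the mean difference, serialized as `+`/`-`.

Pairwise p-values are computed unconditionally rather than gated on the
omnibus test: gating ("protected LSD") would push the per-comparison type-I
error well below nominal, and the engine's calibration target is the
per-pair level. Null simulations at n = 9 × 3 groups put the full route's
per-pair type-I error near 0.05 (the acceptance band is 0.03–0.09).

**No multiplicity correction is applied across variables** — across the 36
spots or the dozens of biometric and lipid variables. This is faithful to
the study's reported procedure and must be kept in mind when reading the
star columns: at 36 spots and α = 0.05, roughly two false flags per
comparison column are expected under a global null.

# The synthetic-cohort generator

`generate_cohort(config, seed)` emulates per-animal data from configured
group summaries; `default_cohort_config()` *is* the study condition —
printed means and standard deviations, n = 9 per group — and its values are
not tuning knobs.

* **Scalar variables** are drawn from a normal distribution truncated below
  at zero whose underlying parameters are solved (`rtnorm_match()`) so the
  truncated distribution has exactly the configured mean and standard
  deviation. Plain truncation of `N(m, s)` would inflate the mean by more
  than the recovery tolerance whenever `m/s` is small (several spot indexes
  have `m/s` near 1.2), which would make the generator disagree with its own
  configuration by construction. Moment matching keeps the round trip exact
  in expectation. The family cannot represent a coefficient of variation of
  1 or more; no configured variable approaches that, and such a
  configuration errors loudly. Log-normal draws were rejected for scalars
  because the printed dispersions are small relative to the means, making
  the truncated normal both adequate and closer to how such assays are
  usually summarized. A variable printed without a standard deviation is
  drawn as a constant (sd = 0).
* **Fatty-acid profiles** are drawn independently per acid and renormalized
  to sum to 100 per animal. No between-acid covariance is published; the
  compositional closure is the only dependence introduced. At the printed
  dispersion scale the closure factor perturbs draws by about 1–2% relative
  on average (the configured means already sum to 99.99–100.01).
* **Densitometry**: per animal (one gel pair) and spot, raw Coomassie
  intensity is log-normal (meanlog = log(50000), sdlog = 0.3 — arbitrary
  densitometry units setting the scale well above the detection limit);
  the target index is drawn by the same moment-matched truncated normal
  from the spot/group summary; FTSC = index × Coomassie. Five low-abundance
  analogue spots (`A`–`E`) are drawn with Coomassie uniformly below the
  detection limit and a strong FTSC signal, so their indexes are undefined
  in every animal, exercising the missing-data path end to end.
* **Reproducibility**: a cohort is a pure function of (config, seed);
  `run_all()` writes the config JSON and an MD5 manifest next to its output
  tables.

**What passing tests do and do not show.** The generator reproduces the
first two moments of every published variable and the independence structure
it assumes. Real cohorts have correlated variables (a heavy animal has a
heavy liver; GSSG and GSH covary within animals), non-normal tails, and
per-gel technical effects. Consequently ratio variables computed from
independently drawn numerators and denominators have heavier tails than
their published per-animal counterparts (the mean of GSSG/GSH draws exceeds
the printed per-animal mean of 2.45, whose smallness implies positive
GSSG–GSH correlation in the real animals). Tests passing on synthetic
cohorts validate the pipeline's arithmetic, routing and calibration — not
distributional claims about real livers.

**Simulation sizes** (chosen to keep Monte-Carlo error well below the
quantities' tolerance bands): 5000 null replicates for engine calibration,
200 cohorts for detection power at the published effect sizes, 500 animals
per group for moment recovery (3-standard-error criterion per variable;
sd-0 variables instead use a sub-printed-precision tolerance because the
compositional closure rescales constants by a factor of order 1e-4).

# Annotation and network summaries

`facet_proportions()` tallies, per gene-ontology facet, the percentage of
annotated proteins carrying each term; multi-term proteins count once per
term, so multi-label facets can sum past 100%. `network_summary()` filters
an edge list at a confidence threshold (default 0.4, the conventional
"medium confidence"), drops isolated nodes, and reports node/edge counts,
degrees and connected components (component detection stands in for
cluster-algorithm output, which depends on external tooling).

The shipped fixtures are **synthetic** and say so in their filenames and
headers: per-protein GO assignments and database edges were never published
for this protein list, and live database queries would drift with database
versions. The annotation fixture is constructed so that its aggregate
percentages equal the published ones — checks against those numbers
document the encoding and are circular by design, not validation. The
published molecular-function percentages are mutually inconsistent as
subset percentages (the four catalytic subclasses sum to 87.5% while
catalytic activity itself is 75.0%), so the fixture treats every term as an
independent label over one facet denominator. Enrichment statistics are out
of scope; the study reports descriptive proportions only.

# Degenerate inputs and numerical choices

* Zero denominators: undefined (`NA`) for per-sample indexes; errors only
  where no result is representable (all-zero ppm channel, zero Coomassie
  lane total, non-positive body weight).
* All-tied nonparametric omnibus returns p = 1; zero pooled MSE gives
  undefined LSD p-values.
* Variables with fewer than two groups of two defined observations are
  skipped by the pipeline's comparison stage with a logged message (the
  low-abundance spots always are).
* Ties in rank tests use midranks; Mann–Whitney p-values use the normal
  approximation with continuity correction for stable behavior at n = 9
  with ties.
* The closure tolerance for validating percentage profiles defaults to 0.5
  points, absorbing printed rounding; generated profiles are validated at
  1e-6.

# Reproducing the printed quantities

`reproduce_printed()` recomputes every derived printed cell from the
packaged printed group means — pure, platform-independent arithmetic — and
reports computed vs printed at printed precision. Exactly reproducible (and
asserted in the acceptance tests): the ω-3 (STD), ω-6 (all groups), MUFA
(STD) and PUFA (STD, HFHS+w3) class sums; all three EPA/DHA ratios; the
DHA (+3.46), EPA (+0.74) and EPA+DHA (+4.20 percentage-point) incorporation
shifts; the adiposity (1.7/2.3/2.3) and hepatosomatic (0.50/0.44/0.43)
indexes; SCD-16 in all groups and Δ6D in STD/HFHS. The remaining class and
panel cells differ in the last printed digit (component rounding or
per-animal averaging) and are reported with `match = FALSE`.

`scripts/acceptance.R` re-derives all of the above from scratch plus the
seeded Monte-Carlo rates (per-pair type-I error, minimum detection rate for
spots with standardized HFHS-vs-STD effects ≥ 1.5, arrow-sign agreement,
and the moment-recovery fraction at n = 500).
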
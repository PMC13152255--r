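---
title: "Methods: point-based variant curation with paired SGE functional evidence"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgecurate)
```

This vignette documents the models, conventions and design choices behind
`sgecurate`: what each stage computes, where the procedure leaves room for
convention and how those conventions were fixed, what the synthetic-cohort
generator does and does not emulate, and the known limitations.

## The point-based classification model

ACMG/AMP evidence codes carry a direction (pathogenic or benign) and a
strength (supporting, moderate, strong, very strong). The point model maps
strength to magnitude 1, 2, 4, 8 — signed positive for pathogenic and
negative for benign evidence — and classifies the arithmetic total:
PV at ≥ 10, LPV 6–9, VUS −1–5, LBV −6 to −2, BV ≤ −7. The integer bands are
exhaustive and disjoint, and the label is monotone in the total; both
properties are enforced by tests across the whole range −20..20.

Conventions the standard leaves open:

- **Strength suffixes.** `_P`, `_M`, `_S`, `_VS` override the family-default
  strength (`PVS` very strong, `PS`/`BS` strong, `PM` moderate, `PP`/`BP`
  supporting), so `PM2_P` is PM2 applied at supporting strength (+1).
  Trailing parenthetical annotations (`"BP7_S (RNA)"`) are comments and are
  ignored for computation.
- **Stand-alone benign evidence.** `BA1` has no point value in the model.
  Rather than invent one, `classify_variant()` short-circuits to BV,
  excludes the code from the total, and flags the result. Curated cohorts in
  this gene region never trigger it; the convention exists so the function is
  total.
- **Duplicate families.** Applying two codes of the same base family (`PS3`
  and `PS3_P`) is rejected rather than summed: a line of evidence is never
  double-counted.

## SGE integration

Each of the two assays reports one of seven categories mapping bijectively
to +4, +2, +1, 0, −1, −2, −4 points; the sign is the binary functional call.
Integration assigns `PS3` (both pathogenic) or `BS3` (both benign) at the
**stronger** of the two levels: |points| 4 → strong, 2 → moderate
(`PS3_M`/`BS3_M`), 1 → supporting (`PS3_P`/`BS3_P`). The max rule reflects
how strong-level evidence was justified in practice (at least one assay in
the strong category) and yields the supporting-level downgrade naturally
when both assays sit at the supporting level. Pairs with opposite signs, or
with exactly one uncertain call, are *discordant* and receive no functional
evidence. Two uncertain calls are *uninformative*: they carry no evidence
either, but are deliberately kept out of the discordant set, which is
defined by at least one definitive call.

`apply_integration()` refuses evidence lists that already contain a
PS3/BS3-family code: functional evidence enters only through integration,
never twice.

## Multifactorial likelihood analysis

The posterior probability of pathogenicity combines a prior with a product
of independent likelihood ratios on the odds scale:

$$\mathrm{posterior} = \frac{\pi \cdot LR}{\pi \cdot LR + (1 - \pi)}$$

The prior $\pi$ is looked up by Align-GVGD grade, falling back to variant
type (nonsense, synonymous, intronic, ...) for ungraded variants. The
shipped `config.yaml` holds the conventional BRCA2 prior values (C0 0.02 up
to C65 0.81; nonsense 0.96; synonymous and intronic 0.02) as *editable
configuration*: priors are maintained in external curation databases, and
the pipeline makes no claim about their authoritative values.

IARC classes ladder on the posterior: class 5 > 0.99; class 4 0.95–0.99;
class 3 0.05 to < 0.95; class 2 > 0.001 to < 0.05; class 1 ≤ 0.001. Two
boundary conventions deserve comment:

- **The 0.001 boundary belongs to class 1.** Posteriors are conventionally
  reported at three decimals, so a full-precision posterior below 0.001 can
  print as 0.001; assigning the boundary value to class 1 keeps the class of
  a reported posterior consistent with the class of the underlying
  full-precision value. All other boundaries are half-open upwards.
- **The LR exclusion window [0.5, 2] is inclusive.** A combined LR this
  close to neutral leaves the posterior dominated by the prior, so no class
  is assigned. Inclusive bounds are the conservative choice (more
  exclusions); the window is configurable.

A combined LR of exactly 0 forces posterior 0 (class 1) for any prior < 1;
prior 1 with LR 0 is an indeterminate 0/0 and raises an error.

## Concordance statistics

Against a clinical reference (five-tier class, or IARC class collapsed as
1–2 benign-side, 3 uncertain, 4–5 pathogenic-side), a functional call is a
**major error** when it directly opposes a definitive class, a **minor
error** when either the call or the class is uncertain but not both, and
concordant otherwise. Percentages are reported to one decimal, rounding
half away from zero (so 1.25% reports as 1.3%); counts are kept internally.

The two datasets are compared with the Bhapkar test of marginal homogeneity
on the k×k cross-tabulation of their paired per-variant agreement
categories. With cell proportions $p_{ij}$, marginal differences
$d_i = p_{i\cdot} - p_{\cdot i}$ ($i = 1..k-1$) and covariance
$v_{ii} = p_{i\cdot} + p_{\cdot i} - 2p_{ii} - d_i^2$,
$v_{ij} = -(p_{ij} + p_{ji}) - d_i d_j$, the statistic $n\,d'V^{-1}d$ is
referred to $\chi^2_{k-1}$. Small tables with empty categories make $V$
singular; the Moore–Penrose generalized inverse is used and the degrees of
freedom drop to rank($V$). A fully degenerate table ($d = 0$, $V = 0$)
returns statistic 0 and p-value 1 by convention. The implementation is
cross-checked in the tests against the closed-form k = 2 reduction
$(n_{12}-n_{21})^2 / (n_{12}+n_{21} - (n_{12}-n_{21})^2/n)$ on 1,000 random
tables and against a 10,000-replicate parametric bootstrap (multinomial
resampling from the symmetrized cell probabilities) on random 3×3 tables.

On the 13-variant discordant cohort the two references behave differently:
the IARC-based comparison of the five informative-LR variants gives
p = 0.84, while the ACMG-based comparison of all 13 gives p ≈ 0.81. Both
are far from significance; the pipeline reports both.

## The synthetic-cohort generator

`simulate_cohort()` emulates the *inputs* of the pipeline, not the assays:

- **True classes** are drawn from `class_mix` (default 10% PV, 10% LPV,
  40% VUS, 30% LBV, 10% BV — a VUS-heavy mix typical of curated cohorts in
  this gene region).
- **Evidence sets** are rejection-sampled from a pool restricted to the
  code families seen in curated BRCA2 cohorts (PVS1, PS1, PM2, PM5, PP1,
  PP3; BS1, BS2, BP4, BP7), with direction-biased inclusion probabilities,
  until the point total lands in the true class's band — so generated
  evidence is always internally consistent with the truth. PS3/BS3 are
  deliberately absent from the pool: functional evidence may only enter
  through SGE integration.
- **SGE pairs** match the truth's direction with a random magnitude
  (1, 2 or 4). With probability `sge_discordance_rate` (default 0.2,
  roughly the discordance observed between published SGE datasets) one
  dataset is forced to contradict the other — sign flip or uncertain, with
  equal probability, mirroring the two discordance modes seen in practice.
  Otherwise each dataset is independently corrupted to the opposite
  direction with probability `sge_error_rate` (default 0.05, a plausible
  per-assay miscall rate).
- **LR components** are lognormal — positivity and multiplicative
  combination make the lognormal the natural family; nothing is claimed
  about the true distribution of clinicopathological LRs. Defaults
  (meanlog +0.6 pathogenic-group / −0.6 benign-group, sdlog 0.4, 3
  components) separate the groups cleanly: the log combined LR is normal
  with mean ±1.8 and sd 0.69, so ~99.5% of pathogenic truths exceed LR 1.

What passing the simulation tests shows: the pipeline's bookkeeping —
band-consistent evidence, discordance accounting, direction of
reclassification, LR arithmetic — is correct against a known truth. What it
does not show: anything about real assay error structure (real SGE
miscalls are correlated with variant class and position, not uniform),
real evidence-code co-occurrence, or real LR distributions.

## Numerical and I/O conventions

- Aggregated points are exact integers; no rounding anywhere in the
  classification path.
- Posteriors and LRs are computed at full precision and written at three
  decimals; percentages at one decimal, half away from zero.
- TSV (UTF-8, header row) is the exchange format. HGVS strings are opaque
  identifiers — no transcript-aware normalization. The Unicode minus
  (U+2212) that typeset tables print is accepted on input; ASCII is always
  emitted. Identical input yields byte-identical output (stable column
  order, fixed formats).
- SGE categories may be given as level names or signed points; the
  bijection makes the forms interchangeable.

## Problem sizes

The shipped analyses run on the two in-package cohort tables (13 and 29
variants) and on simulated cohorts of 300–1,000 variants; the property
suites use a 100×100 posterior grid, 1,000 random 2×2 tables and ten
bootstrap-checked 3×3 tables. These sizes give stable Monte-Carlo
comparisons while keeping the full suite under a minute on one core.

## Known limitations

- Evidence codes are inputs: the package performs no frequency, in-silico
  or splicing analysis to derive them.
- SGE categories are inputs: no function-score modelling or calibration of
  the upstream assays is attempted.
- LR components are inputs or simulated: the estimation machinery that
  produces them from pedigree and pathology records is out of scope.
- The Bhapkar test is asymptotic; for very small cohorts (the 5-variant
  IARC comparison) the chi-square reference is approximate, which is why
  the implementation is bootstrap-checked in the tests.
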
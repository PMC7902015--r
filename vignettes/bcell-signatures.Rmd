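---
title: "Methods: expression signatures and proliferation analysis of B cell subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression signatures and proliferation analysis of B cell subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsig)
```

# Scope and study design

`bsig` implements the computational chain used in case-control microarray
studies of sorted B cell subsets in systemic lupus erythematosus (SLE):
naive B cells, memory B cells, and plasmablasts (operationalized as
CD38+CD43+ B cells) from healthy controls (HC) and patients, typically
four donors per group. The canonical findings such a study looks for are

* a type I interferon (IFN) signature elevated in SLE samples of *every*
  subset,
* a cell-cycle signature elevated *only* in SLE plasmablasts, and
* a module of genes whose expression profile tracks an anchor
  transcription factor (FOXM1) that drives the proliferative program.

Alongside the expression chain, the package analyses dye-dilution
proliferation experiments (CellTrace-style labelling, where a covalent
dye halves at each division) and annexin/viability apoptosis gating.

Every stage is implemented against plain containers (a numeric matrix
with gene and sample identifiers; data frames for annotations and
results) and validated with typed error conditions, so the chain is
fully testable on synthetic data with known ground truth.

# The moderated t-test

Differential expression uses an empirical-Bayes moderated t-statistic.
For gene $g$ compared between groups of sizes $n_a$, $n_b$ within one
subset, the pooled variance $s_g^2$ has $d_g = n_a + n_b - 2$ degrees of
freedom. The hierarchical model is

$$s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \,\chi^2_{d_g}/d_g, \qquad
  \frac{1}{\sigma_g^2} \sim \frac{\chi^2_{d_0}}{d_0 s_0^2},$$

a scaled-inverse-chi-square prior on the true variances. The posterior
variance is the precision-weighted compromise

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated statistic
$t_g = (\bar x_b - \bar x_a)/(\tilde s_g\sqrt{1/n_a + 1/n_b})$
follows a Student-$t$ with $d_g + d_0$ degrees of freedom. Two limits
anchor the implementation: $d_0 = 0$ reproduces the classical pooled
t-test exactly (a test asserts agreement to $10^{-10}$), and
$d_0 = \infty$ shrinks fully to $s_0^2$ with a Normal reference.

## Fitting the prior

`fit_variance_prior()` moment-matches on log variances. Writing
$z_g = \log s_g^2$ and $e_g = z_g - \psi(d_g/2) + \log(d_g/2)$
(with $\psi$ the digamma function),

$$\mathrm{E}[e_g] = \log s_0^2 - \psi(d_0/2) + \log(d_0/2), \qquad
  \mathrm{Var}[z_g] = \psi'(d_g/2) + \psi'(d_0/2).$$

The excess of the empirical variance of $z$ over the sampling term
$\psi'(d_g/2)$ identifies $d_0$ through a trigamma inversion, solved by
monotone Newton iteration to relative tolerance $10^{-8}$
(`trigamma_inverse()`). If the excess is non-positive there is no
evidence of variance heterogeneity and the prior degenerates to
$d_0 = \infty$ with $s_0^2$ set to the geometric mean of the observed
variances, so that identical inputs return exactly their common value.
Fewer than 10 usable genes is an error: with so little information the
ordinary t-test is the honest choice. The fitted pair is cross-checked
in the test suite against an independent, widely used moderated-t
implementation on identical data.

## DEG calling

Fold changes use the signed convention of array software: with linear
ratio $r = 2^{\bar x_b - \bar x_a}$, the reported value is $r$ when
$r \ge 1$ and $-1/r$ otherwise, so down-regulation appears as a negative
magnitude and $|fc| \ge 1$ always. A gene is called up when
$p < 0.05$ and $fc \ge 2$, down when $p < 0.05$ and $fc \le -2$
(equivalently, below 0.5-fold). No multiple-testing correction is
applied by default, matching the thresholding convention the package
targets; `call_degs(adjust = "BH")` enables Benjamini-Hochberg.

Normalization is a per-array 75th-percentile shift on the log2 scale —
the documented default for one-color arrays — with the percentile
defined by linear interpolation between order statistics
(`quantile()` type 7), stated explicitly so the unit-test oracle is
exact.

## Over-representation

`ora_fisher()` tests each gene set with a one-sided Fisher's exact test
(enrichment direction) on the 2x2 table of DEG membership against set
membership within the tested background, significant at $p < 0.01$.
Only the combinatorial over-representation test is provided; proprietary
knowledge-base activation scores are out of scope. The implementation is
verified against exhaustive enumeration of all possible DEG draws on
small backgrounds.

# The signature score

For a gene set, each member's row is first mapped to the linear scale
($2^{x}$) and divided by its maximum across **all** samples, so every
usable gene's maximum is exactly 1; a sample's score is the sum of these
normalized values. Scores therefore lie in $[0, m]$ for $m$ usable
genes, and a sample attaining every row maximum scores exactly $m$.

Two conventions deserve justification because the recipe leaves them
open:

* **Linear scale.** A ratio-to-max is only meaningful on a nonnegative
  scale; applied to log2 values it would be offset-sensitive (and
  ill-defined for negative normalized values). The choice is recorded in
  the result's `scale` attribute and exposed as a flag
  (`scale = "asis"` uses values unchanged).
* **Row maximum across all samples jointly.** All six
  (subset, group) cells are plotted and compared on one score axis;
  per-subset maxima would break cross-subset comparability.

Missing set members are dropped and reported, never imputed, and the
usable-gene count accompanies every score. Single-gene displays use the
analogous ratio-to-minimum (`min_normalize_gene()`), where the minimum
maps to exactly 1.

Score comparisons (`compare_scores()`) run one-way ANOVA across the six
design cells with Tukey HSD adjusted pairwise p-values, plus per-subset
two-sample pooled-variance t contrasts — standard routines delegated to
`stats`.

# The similar-entities screen

`find_similar_entities()` computes the Pearson correlation between an
anchor gene's per-sample profile and each candidate's, across all
samples, and selects candidates inside the closed band
$[r_{\min}, r_{\max}]$, default $[0.6, 1.0]$. Closed at both ends: a
candidate at exactly the boundary is selected. Pearson is the default
(Spearman by flag); the profile spans all samples rather than one
subset, because the screen's purpose is to find genes sharing the
anchor's cross-subset pattern (high only in SLE plasmablasts).
Zero-variance profiles have no defined correlation and are excluded with
a warning. A brute-force double-loop correlation is the test oracle.

# Proliferation and apoptosis readouts

Dye-dilution peaks sit at $I_0/2^i$ for generation $i$, equally spaced
in log space. `assign_generations()` assigns each event to the nearest
log-scale peak center, with boundaries at the geometric means of
adjacent centers; events dimmer than the last boundary go to the final
generation. Fixed geometric boundaries (not mixture fitting) keep the
assignment deterministic and testable.

The proliferation index over generation percentages $N_i$ is

$$\mathrm{PI} = \frac{\sum_{i\ge 0} N_i}{\sum_{i\ge 0} N_i/2^i},$$

total cells over founder-equivalents — the average number of divisions.
Generation 0 is included in both sums; this reading is fixed by the
closed forms it must satisfy ($\mathrm{PI}=1$ when nothing divides,
$\mathrm{PI}=2^k$ when every cell has divided $k$ times) and by the
exact branching identity $\text{founders} = \sum_i \text{count}_i/2^i$,
which the test suite verifies against per-cohort bookkeeping. Some
laboratories exclude the undivided peak; `exclude_gen0 = TRUE` exposes
that convention without asserting it as the default. PI is invariant to
whether $N_i$ are counts or percentages, and a test asserts it.

Apoptosis gating follows the annexin V / viability-dye convention:
annexin-negative events are live, annexin-positive viability-negative
events are early apoptotic, double positives are late apoptotic. The
three fractions partition the events.

# The synthetic-data generator

`simulate_expression_study()` emulates the 3-subset x 2-group x
4-donor design on the log2 scale:

$$x_{gs} = \mu_g + \beta_{g,\mathrm{subset}(s)} + \Delta_{g,s}
           + a_g f_s + \varepsilon_{gs},$$

with per-gene baselines uniform on [4, 12] log2 units (the dynamic range
of a one-color array), per-(gene, subset) offsets
$\beta \sim N(0, 0.5^2)$, and residual noise
$\varepsilon_{gs} \sim N(0, \sigma_g^2)$ whose gene variances are drawn
from the scaled-inverse-chi-square prior with scale $s_0 = 0.5$ and
$d_0 = 4$ — so the moderated-t prior is well-specified by construction
and its recovery is a meaningful test. The planted effects $\Delta$ are
a 23-gene IFN set at +1 log2 in all SLE samples and a 231-gene
cell-cycle set at +1 log2 in SLE plasmablasts only; defaults mirror the
motivating study's set sizes and donor counts, with effect and noise
magnitudes chosen once as realistic for arrays of this type.

The FOXM1-like module is driven by a latent factor $f_s$, nonzero only
in SLE plasmablast samples ($f \sim N(2, 1)$ there). Module gene
loadings $a_g$ are calibrated so each gene's correlation with the factor
equals the configured loading (default 0.8), accounting for the gene's
*total* non-factor variation (residual noise plus its mean-profile
variation across samples). The anchor itself is generated as an exact
readout of the factor — flat at its baseline except where the factor
acts — modelling the transcription factor that *is* the module's
driver; with a noisy anchor the gene-anchor correlations would
systematically undershoot the configured gene-factor loading. Planted
gene sets are disjoint by default so recovery tests attribute signal
unambiguously.

An optional donor random effect (`donor_sd`, default 0) exposes
donor-to-donor variance as a variance component without asserting a
particular magnitude, since the real donor structure is unknown.

`simulate_division_experiment()` models founders passing through a
per-generation Bernoulli progression chain; a cohort whose chain stops
at generation $i$ contributes $2^i$ events with lognormal dye intensity
(median $I_0/2^i$, configurable CV), and apoptosis channels drawn from
Gaussian classes with configured fractions. Only the terminal
generation distribution matters for the PI, so no division timing is
modelled.

## What the generator does not emulate

Probe-level array artifacts, background correction, batch effects,
identifier ambiguity, heavy-tailed or correlated residual noise beyond
the single module factor, cell death during culture, compensation or
doublets in the flow data. Passing recovery tests therefore establishes
the correctness and calibration of the *methods* under their stated
model, not robustness to every failure mode of real data.

# Numerical choices and degenerate inputs

* TSV with 17 significant digits for expression values (bit-exact
  round trips) and 9 for result tables; no quoting, so embedded tabs
  are an error rather than silent corruption.
* Trigamma inversion: monotone Newton, relative tolerance $10^{-8}$,
  with asymptotic branches for extreme arguments.
* Zero-variance genes: moderated t of a zero difference is 0
  ($p = 1$); a nonzero difference over a zero posterior variance is
  $\pm\infty$ ($p = 0$).
* All-equal scores: ANOVA is reported as $F = 0$, $p = 1$ rather than
  the indeterminate 0/0.
* Undefined correlations (zero variance) are reported missing, never
  coerced to 0.
* Every simulator is seed-deterministic; the pipeline derives per-stage
  sub-seeds from one run seed by a counter scheme kept below $2^{31}$.

# Verification scales

The test suite evaluates: the classical-t limit on 100 random 4v4
instances; type-I calibration on twenty 5000-gene null studies (the
p < 0.05 rate must sit within 3 binomial SEs of 0.05); prior recovery on
100 draws of 5000 variances from the stated prior (within 15% in >= 90%
of replicates); the subset-restricted signature pattern on one hundred
5000-gene studies; module recovery over 50 seeds (median sensitivity
>= 0.8, median decoy rate <= 5% in the [0.6, 1.0] band); PI identities
on arbitrary simulated cohorts to $10^{-9}$; and ORA against exhaustive
enumeration. These sizes were chosen to make the Monte-Carlo bounds
meaningful while keeping a full run fast on a laptop.

One subtlety: the joint signature-pattern event requires
non-significance of the cell-cycle score in both unaffected subsets,
each a true null, so its expected success rate is about
$0.95^2 \approx 0.90$ — the criterion sits at its own bound by
construction, and measured rates legitimately hover around 0.9.

# Known limitations

* The DEG rule is deliberately uncorrected for multiple testing (the
  convention it reproduces); interpret absolute DEG counts accordingly.
* The signature score has no competitive null (it is a plain normalized
  sum, not a GSEA-like statistic); between-group comparisons rely on the
  ANOVA/t machinery.
* Generation assignment assumes log-equidistant peaks anchored at a
  known undivided intensity; a mis-specified `gen0_mean` shifts all
  assignments coherently.
* Printed headline numbers from any particular real study (absolute DEG
  counts, the exact size of a similar-entities list) depend on raw-data
  preprocessing outside this package's scope and are not reproduction
  targets; the package's claims are the calibration and recovery
  properties above.
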
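---
title: "Methods: the dcfbiodeg biodegradation analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dcfbiodeg biodegradation analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcfbiodeg)
```

dcfbiodeg models the quantitative chain of a bench-scale pharmaceutical
biodegradation study: how fast the parent compound disappears, how toxic it
is to the degraders and to a sentinel organism, what transformation
products linger, and how the degrading community restructures. This
vignette documents the models, the parameters that matter, the synthetic
data used for validation, and the numerical choices behind the
implementation.

## Degradation kinetics

Two decay laws are implemented. Simple first-order (SFO),

$$M_t = M_0 e^{-kt}, \qquad DT_{50} = \ln 2 / k,$$

describes a single exponential dissipation. The hockey-stick (HS) model is
a continuous biphasic variant: a fast rate $k_1$ up to a breakpoint $t_b$,
then a slow rate $k_2 \le k_1$,

$$M_t = \begin{cases} M_0 e^{-k_1 t} & t \le t_b \\
M_0 e^{-k_1 t_b} e^{-k_2 (t - t_b)} & t > t_b. \end{cases}$$

Its half-life is $\ln 2 / k_1$ when that falls inside the fast phase, and
otherwise $t_b + (\ln 2 - k_1 t_b)/k_2$; when $k_2 = 0$ and the fast phase
never reached 50%, the half-life is reported as `Inf` (with a flag) rather
than an error, because a plateau is a scientifically meaningful outcome.
Both DT50 closed forms are validated in the test suite against bisection
root-finding on the model curves themselves.

**Fitting.** Parameters minimise the residual sum of squares under bounds
($M_0 > 0$, rates $\ge 0$, $t_b$ inside the observed time range). The HS
model is parameterised as $(M_0, k_1, r, t_b)$ with $k_2 = r k_1$,
$r \in [0, 1]$, which enforces $k_1 \ge k_2 \ge 0$ without constraint
machinery. L-BFGS-B is run from multiple starts: rate constants from a
log-linear regression of the positive concentrations, the breakpoint from
a grid over interior observed times, plus one start at the SFO solution
with $r = 1$ — the last guarantees the nested HS fit never ends up worse
than SFO. Replicated measurements are averaged per time point before
fitting, the convention of environmental-fate kinetics evaluation. A rate
constant the optimiser leaves below $10^{-10}\,d^{-1}$ is reported as
exactly zero: at double precision it is indistinguishable from no decay,
and snapping it keeps the DT50 of a flat series at `Inf` instead of a
meaningless astronomical number.

**Goodness of fit.** The χ² error assessment asks: assuming measurements
carry a relative error of `err_pct` percent of the mean observed
concentration, is the residual scatter compatible with that error? The
statistic is

$$\chi^2_{calc} = \frac{\sum_i (o_i - p_i)^2}{(\tfrac{err}{100}\bar{o})^2},$$

compared against the 0.95 quantile of $\chi^2$ at $df = n - n_{par}$. The
*scaled error* is the smallest error percentage at which the test passes,
$100/\bar{o}\,\sqrt{SSR/q_{0.95}}$; by construction, re-evaluating
$\chi^2_{calc}$ at that percentage returns exactly the tabulated quantile,
a self-consistency the tests assert. The default `err_pct = 15` is the
conventional starting point of this style of assessment and is exposed as
an argument. Model selection minimises the scaled error, with ties broken
toward fewer parameters (parsimony).

## Dose–response IC50

Viability is the OD600 ratio of treated to control cultures, in percent
(values above 100 — stimulation — are allowed). The dose–response curve is
the second-order polynomial $y = a u^2 + b u + c$ in $u = \log_{10} C$,
fitted by ordinary least squares on all individual measurements (fitting
on duplicates rather than means preserves degrees of freedom and is
identical for balanced designs). Base-10 logs are the default because dose
ladders in this field are decadic; the base is an argument.

The IC50 solves $a u^2 + b u + c = 50$. Two choices needed fixing where a
quadratic gives two roots: roots inside the tested dose range (extended by
0.3 log units of tolerance) are preferred, and between two admissible
roots the one on the *declining* limb ($2au + b < 0$) is taken, since an
inhibitory concentration is defined where viability falls through 50%. A
crossing outside the tested range is still returned but flagged
`"extrapolated"` — high-tolerance organisms routinely have IC50s beyond
the highest feasible dose, and hiding the estimate would discard the
result practitioners actually report; the flag preserves the caveat. A
curve that never crosses 50% yields `NA` with flag `"not_attained"`.

## Microtox-style ecotoxicity

The luminescent-bacteria assay measures light output at 0 and 15 min for a
1:2 dilution ladder of the sample (90.9, 45.45, 22.73, 11.36 % v/v by
default). Toxicant-free controls estimate the natural drift of light
output as $f = \overline{i_{15}/i_0}$; the inhibition of a sample cuvette
is $H = 100 (f i_0 - i_{15})/(f i_0)$ and the effect ratio is
$\Gamma = H/(100 - H)$, lost light over remaining light. Near the EC50,
$\log_{10}\Gamma$ is linear in $\log_{10}$ concentration, so the EC50 is
$10^{-\beta_0/\beta_1}$ from that regression, i.e. the dilution where
$\Gamma = 1$. Cuvettes with $H \le 0$ (stimulation) or $H \ge 100$ carry
no usable information and are flagged out of the regression rather than
erroring; a non-positive slope flags a non-monotone response. Toxic units
are $TU = 100/EC_{50}$, reported rounded half-away-from-zero to one
decimal — the rounding convention of acute-toxicity tables, applied only
at the reporting edge (unrounded values are retained internally).
Replicated assays report mean ± sd of the per-replicate EC50s and TUs.
Hazard classes follow the Persoone toxic-unit bands with inclusive lower
bounds: `< 0.4` none, `[0.4, 1)` slight, `[1, 10)` acute, `[10, 100)`
high, `>= 100` very high acute toxicity.

## Metabolite summaries

Transformation products come in two reporting modes: quantified analytes
(µg/L with a limit of quantification, e.g. hydroxylated metabolites at
LOQ 0.1 µg/L) and peak-area-only analytes where no standard exists. The
summary per analyte is: first detection time, peak time and value, final
value within the horizon, and a persistence flag. Values below the LOQ are
treated as non-detections for the flags but retained numerically (no
substitution rule is applied); for peak-area analytes any positive area is
a detection. Summaries are invariant to prepending pre-detection zero
records, which the tests assert.

## Community summaries

ASV count tables are handled as samples-by-ASV integer matrices (the
convention of R community-ecology tooling), with data-frame input
accepted. Rarefaction subsamples each sample's reads without replacement
(multivariate hypergeometric) to a fixed depth, deterministically for a
given seed — the seed is part of the function contract because rarefied
analyses must be reproducible. Alpha diversity is computed from relative
abundances: observed richness, Shannon entropy in natural-log units (the
default of the reference community-ecology implementation, against which
the tests cross-check; the log base is an argument), and inverse Simpson.
Genus composition pools reads by genus with unassigned ASVs in an `"NA"`
category; percentages per sample sum to 100. For display, genera below a
0.1% threshold *in every sample* can be pooled into `"Other"` — the
underlying full table is what analyses should consume. Venn overlap
counts ASVs present (count > 0, conventionally after rarefaction) in
both, one, or the other of two samples and reports the shared percentage
unrounded.

## Synthetic data: what it emulates and what it does not

The generators reproduce each assay's *design* and noise structure so the
pipeline can be validated end to end:

- `gen_degradation()`: the 9-point sampling schedule (0, 0.5, 1, 2, 5, 7,
  14, 21, 28 d) from a 10 mg/L spike, with additive Gaussian noise
  (default sd 0.2 mg/L, i.e. 2% of the spike — a plausible HPLC
  repeatability) truncated at zero. The HS scenario defaults to
  $k_1 = 1.05$, $k_2 = 0.002\,d^{-1}$ with breakpoint 1 d, placing the
  rate change just after the fast initial dissipation.
- `gen_dose_response()`: the 10–5000 mg/L dose ladder in duplicate;
  quadratic truth $(-8, 5, 95)$ chosen to stay non-negative over the
  ladder and cross 50% near 500 mg/L; Gaussian noise (default sd 5
  percentage points) floored at 0.
- `gen_microtox()`: the 1:2 dilution ladder; $\Gamma$ exactly log-linear
  in dilution with slope 2 per decade; multiplicative log-normal noise on
  intensities; control pairs embedding the drift ratio $f$.
- `gen_asv_tables()`: a rich, fairly even "before" sample (111 of 148
  ASVs present) at depth 95,729 and a swept "after" sample (one genus at
  88.9%, 60 ASVs present) at depth 3,231 — the order-of-magnitude depth
  asymmetry such paired datasets show. Genus-level target proportions are
  preserved exactly (the within-genus Dirichlet only redistributes within
  a genus), so the dominant genus' realised share differs from target
  only by multinomial sampling error — about 0.55 percentage points sd at
  depth 3,231.

What passing tests on these data do **not** show: real chromatography has
heteroscedastic, occasionally censored errors rather than constant
Gaussian noise; real viability curves need not be quadratic over the whole
dose range; real luminescence series deviate from log-linearity far from
the EC50; and real amplicon data carry compositional, overdispersed
(beyond Dirichlet-multinomial) structure, chimeras and contamination that
the generator does not model. Parameter recovery on synthetic data is a
check of the estimation machinery, not of the models' adequacy for any
particular organism.

## Validation problem sizes

The packaged tests exercise: 1,000 randomised parameter draws for the
DT50-vs-bisection equivalence; 200 seeded replicates each for SFO and HS
rate-constant recovery at noise sd 0.2 mg/L (median relative errors below
5% and 10% respectively, and the 90% central interval of the SFO rate
covering the generating value); 100 randomised admissible quadratics for
the IC50 round trip; 200 seeded replicates of the Microtox pipeline at 5%
multiplicative noise (median EC50 error under 10%); and the default
community scenario's dominance share within 1 percentage point of target.
These sizes give stable medians and quantiles while keeping the default
test run fast.

## Known limitations

- Only SFO and HS kinetics are implemented — no DFOP, FOMC or
  metabolite-formation kinetics, and no profile-likelihood confidence
  intervals on kinetic parameters.
- The IC50 machinery is tied to the quadratic log-dose model; 4PL/5PL
  logistic fits are out of scope.
- The ecotoxicity module covers the 15-min endpoint and the log-linear
  gamma model only.
- Community analysis stops at per-sample summaries and pairwise overlap;
  beta diversity, ordination and differential abundance belong to
  dedicated ecology packages.
- The spreadsheet-solver optimiser used in many published kinetic analyses
  is not reproducible; this package's multi-start bounded least squares is
  defined instead by its recovery post-conditions, which the tests verify.
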
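---
title: "Modelling and optimizing multi-response extraction experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing multi-response extraction experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmopt)
```

This vignette documents the models, conventions and numerical choices
behind `rsmopt`, in the spirit of a methods section: what each stage
assumes, which tuning parameters matter and why their defaults are what
they are, and what the shipped data can and cannot support.

## The study system

The packaged experiment (`coffee_husk_design()`) is a heat-assisted aqueous
extraction of phenolic compounds from milled coffee husk, run as a
four-factor, three-level Box–Behnken design: temperature 30–100 °C, time
5–90 min, acidity 0–2 % citric acid and solid-to-liquid (S/L) ratio
0.02–0.05 g husk per mL water. Seven responses are measured on each of the
27 runs, all in mg per g dry husk: total phenolic compounds (TPC, gallic
acid equivalents), total flavonoids (TF, quercetin eq.), total flavanols
(TFL, catechin eq.), proanthocyanidins (PAC, cyanidin chloride eq.), total
phenolic acids (TPA, caffeic acid eq.), *ortho*-diphenols (TOD, caffeic
acid eq.) and ABTS antioxidant capacity (AC, Trolox eq.). The tabulated
values are means of triplicate assays, printed to two decimals; the
replicate standard deviations are carried in `*_sd` columns but are not
used in fitting.

## Coded variables and the design

Every factor is coded ascending, $X_i = (x_i - x_{0,i})/\Delta x_i$ with
$x_{0,i}$ the centre of the natural range and $\Delta x_i$ the half-range,
so low/centre/high map to $-1/0/+1$ for all factors, including the S/L
ratio (0.02 g/mL $\to -1$). This is the only direction consistent with the
signs of the fitted coefficients on the packaged data (TPC falls as the
S/L ratio rises, so $\beta_4 < 0$ requires 0.05 $\to +1$).

A generated Box–Behnken design (`bbd_design()`) consists, for $k$ factors,
of all $\binom{k}{2}$ factor pairs at the four $\pm1$ sign combinations
with the remaining factors at centre, plus `n_center` centre replicates —
for $k=4$, 24 edge runs in which exactly two coded coordinates are
non-zero. Each factor is therefore at $-1$ in 6 runs, $+1$ in 6 runs and
$0$ in 15 runs when `n_center = 3`. No randomization or blocking is
applied; the run order is deterministic (pairs lexicographic, signs
$(-,-),(+,-),(-,+),(+,+)$, centres last) because the fitted model is
order-invariant.

## The second-order model and its ANOVA

Each response is fitted in coded space by ordinary least squares to the
full quadratic
$Y = \beta_0 + \sum_i \beta_i X_i + \sum_i \beta_{ii} X_i^2 +
\sum_{i<j} \beta_{ij} X_i X_j$
(15 coefficients, 12 residual degrees of freedom at $n=27$). The model
assumes independent homoscedastic Gaussian errors around a smooth
second-order mean surface; with triplicate-mean responses this is a
reasonable working assumption, though the replicate variances are not
propagated.

Per-term inference uses drop-one (Type III) partial sums of squares:
$SS_j$ is the rise in residual sum of squares when term $j$ alone is
removed, $F_j = SS_j/MSE$ with 1 and $n-p-1$ degrees of freedom, which for
single-degree terms equals the squared coefficient $t$-statistic. A term's
**contribution** is $100\,SS_j/SST$; group rows (linear, quadratic,
interaction) sum their members and the model row carries $100\,R^2$. On a
Box–Behnken design the linear and interaction columns are mutually
orthogonal but the quadratic columns are not, so partial group sums can
exceed $100\,R^2$ slightly; this is a property of the convention, not an
error. Sequential (Type I) sums of squares, which add up exactly to the
model sum of squares, are available via `anova(fit, type = "sequential")`.

**Model reduction** (`reduce_model()`) is a single pass: terms with
full-model $p < \alpha$ (default $\alpha = 0.05$, two-sided $t$) are
retained and the set is closed under hierarchy (parents of retained
quadratic/interaction terms are added back) before one refit. Iterative
backward elimination is deliberately not used: the single pass is
reproducible, cheap, and is the procedure that matches the simplified
models reported for this experiment.

**Natural-unit equations** (`natural_coef()`) substitute the coding
transform into the coded polynomial and collect monomials, so coded and
natural forms predict identically (round-trip tested to 1e-9 at every
design point). Natural coefficients are not comparable across factors —
that is what the coded and standardized forms are for.

## Adequacy metrics

`r_squared()` is $1 - SSE/SST$ about the observed mean; `rmse()` uses
denominator $n$ (not $n-p$), so it measures raw prediction spread, and
`aad()` is the absolute average deviation in percent. Two AAD conventions
circulate in the extraction literature; the default here is the mean
absolute relative deviation with the *predicted* value in the denominator,
$100\cdot\frac1n\sum_i |Y_{pre,i}-Y_{exp,i}|/Y_{pre,i}$, which is the form
consistent with the comparison table of the packaged study (its literal
squared variant, without a square root, is available as
`form = "squared"` and yields values an order of magnitude smaller).
Because a full OLS model's residual sum of squares can only grow when
terms are removed, the full model never has worse in-sample RMSE than its
reduced counterpart — a useful sanity invariant, not a statement about
out-of-sample behaviour.

## The MLP surrogate

`mlp_surrogate()` trains the architecture standard in this literature: one
hidden layer of 10 tanh ("tansig") neurons and a linear ("purelin")
output, per response — 61 free parameters for 4 inputs. Inputs and output
are min–max scaled to $[-1,1]$ over the full design (for design points
this coincides with the coded values), the companion convention of tanh
networks. Weights start uniform in $[-0.5, 0.5]$; training minimizes the
training-set MSE by BFGS with analytic gradients.

With 27 data points split 19/4/4 (train/validation/test, drawn uniformly
at random) this model is heavily over-parameterized, and three safeguards
matter far more than the optimizer:

* **Checkpointing / early stopping.** Parameters are recorded every 10
  BFGS iterations up to `max_epochs` (default 500). Classical early
  stopping — the validation-error argmin along the trajectory — is what
  `select = "validation"` implements.
* **Restarts with fresh splits.** Each restart (default `restarts = 100`)
  draws a new random split *and* new initial weights, mirroring toolboxes
  that re-divide the data on every training call. All randomness descends
  from the single `seed`.
* **A small weight-decay grid.** Each restart is run at L2 penalties
  $\lambda \in \{10^{-4}, 3\times10^{-3}, 3\times10^{-2}\}$ on the weights
  (not biases). Decay bounds how violently the network can curve between
  design points; which level is right depends on the response's noise, so
  all three candidates enter the selection pool.

Selection across the pooled checkpoints defaults to the lowest MSE over
*all* runs (`select = "overall"`). This mirrors the workflow this model
family is reported with — many candidate networks trained, the one with
the best fit statistics kept — and it is the only rule that reliably
yields networks fitting all 27 points well. Its price should be stated
plainly: because held-out points participate in selection, the overall
R² of the selected network is an optimistically biased estimate of
generalization. For honest generalization assessment use
`select = "validation"` and judge the network on its own test subset;
expect substantially lower (and noisier) numbers, since 4 validation
points are a weak selection signal. The restart pool must be large
because selection is also the only guard against bad BFGS local minima:
with 10 neurons the loss surface has many, and with few restarts the
noisier responses (TF, PAC) routinely fall short of the fit quality the
smoother responses reach.

## Desirability optimization

Each response enters as a Derringer one-sided "maximize" ramp:
$d = 0$ at or below $L$, $1$ at or above $T$,
$((y-L)/(T-L))^{w}$ between, with $L$/$T$ defaulting to the observed
response minimum/maximum in the design and $w = 1$ — the defaults of the
design-of-experiments software this literature uses when no bounds are
specified. The overall desirability $D$ is the geometric mean, so any
response at $d=0$ vetoes a candidate. $D$ is maximized by an exhaustive
grid (default 21 points per axis over the natural ranges, deterministic)
followed by a bounded quasi-Newton polish confined to the winning grid
cell. Because multi-response optima in time-like factors are often
plateaus or twin peaks, the best grid point at coded distance ≥ 1 from the
first optimum is polished as a second candidate and reported alongside;
on the packaged data both optima sit at the 100 °C / 0 % acid /
0.02 g mL⁻¹ corner and differ only in extraction time, with $D$ within a
few percent.

Validation uses the coefficient of variation of a {predicted,
experimental} pair, $100\,\mathrm{sd}/\mathrm{mean}$ with the sample
($n-1$) standard deviation, i.e.
$100\,|pred-exp|/(\sqrt2\,\overline{y})$ — the convention that reproduces
the published validation values from their printed pairs.

## Chemometrics of the extract panel

`extract_panel()` assembles the 7-sample panel: the four aqueous extracts
(optimal and suboptimal time, milled and raw husk), the organic free and
bound fractions, and the organic total, over the 7 assay responses, the
18 UPLC-quantified compounds and their sum (`total_uplc`). Two
conventions matter:

* **The organic total is a sample.** Correlations computed over the six
  extracts alone do not reproduce the published associations; including
  the total column (the seventh point) does, exactly.
* **Below-detection entries are zeros** for correlations (`missing =
  "zero"`), since absence of a peak is informative about concentration;
  `missing = "na"` switches to pairwise exclusion (correlations) or
  variable-mean imputation (PCA, clustering).

All multivariate analyses autoscale variables (mean 0, SD 1), mandatory
here because assay responses (mg g⁻¹) and compound concentrations
(µg g⁻¹, spanning 0.2–1400) differ by orders of magnitude. PCA is the SVD
of the autoscaled matrix with component signs canonicalized
(largest-magnitude loading positive). PLS is single-response NIPALS;
coefficients are reported back on the original scale and, for importance
ranking, on the autoscaled scale (`standardized = TRUE` in
`pcr_coefficients()`, `coefficients_std` in the PLS fit) — raw-scale
coefficients are dominated by the units of the smallest-variance
variables and must not be ranked. VIP scores use the standard weights
formula, whose squared scores average to 1. Clustering is average-linkage
on Euclidean distances of the autoscaled panel. One tabulated value (TPA
for the raw husk at the suboptimal condition, 23.64) is inconsistent with
its neighbours and is suspected to be a misprint; it is stored as printed
and simply not used as a validation anchor.

## The synthetic generator

`simulate_bbd()` draws a Box–Behnken design and adds i.i.d. Gaussian noise
to a known coded quadratic surface. Its defaults are the study's own
conditions: the full TPC coefficient set as truth and $\sigma = 0.16$, the
residual scatter of that fit, with 3 centre points. The generator emulates
the *mean-model* structure only — it does not simulate replicate
structure, heteroscedasticity, assay calibration error or run-order
drift. Tests that pass on synthetic data therefore certify the estimation
machinery (unbiasedness, coverage, detection power at the study's
signal-to-noise), not robustness to those real-data features.

## Numerical choices and degenerate inputs

OLS is solved by QR decomposition; rank deficiency is an error
("singular design"), not a silent pseudo-inverse. Coefficient p-values
use $n-p-1$ degrees of freedom; significance stars follow the usual
0.05/0.01/0.001 levels. Prediction outside the coded unit cube warns but
proceeds (the quadratic extrapolates smoothly; the warning marks where it
is unsupported). A reduction that retains nothing returns the
intercept-only model with a warning. The desirability geometric mean
clamps at machine-minimum before the log to avoid $-\infty$; exact zeros
veto via a separate mask. Correlation pairs with fewer than 3 complete
observations are flagged as not computed rather than returned as ±1.

## Known limitations

* The tabulated responses are printed to two decimals. Refitted statistics
  carry a propagated rounding error of about $10^{-4}$ on $R^2$ and a few
  hundredths on $F$; two interaction terms (temperature×acidity for TPC,
  temperature×S/L for TPA) sit at $p = 0.0506$ and $0.0519$ — a rounding
  hair above the 0.05 retention threshold, so single-pass reduction keeps
  slightly smaller sets than published for those two responses.
* The tabulated TF and PAC columns are internally inconsistent with their
  published fits (the TF centre replicates cannot produce the published
  intercept; the PAC column yields materially different coefficients), so
  those two responses' published fit statistics are not recoverable from
  the printed data at any precision. All other responses reproduce to
  printed precision.
* The exact split membership, initialization and epoch budget behind the
  published ANN fits are unrecoverable; ANN quality is therefore asserted
  as a bound (overall $R^2 \ge 0.9$ under the documented selection rule),
  with the selection bias caveat above.

## Problem sizes used in the test suite

The suite fits all models on the 27-run dataset; property-style checks use
200 simulated designs for unbiasedness, coverage and power, 100 seeds for
split-coverage, and 100-restart MLP training per response for the fit
bound — sizes chosen so each property is tested at the study's own scale
while the whole suite stays in the low minutes on one core.
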
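---
title: "Short-form construction and validation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-form construction and validation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortscale)
```

shortscale builds short-form psychometric instruments from ordinal
questionnaire data and runs the reliability and validity workflow that
accompanies such a reduction. This vignette explains the statistical
models behind each stage, the tunable parameters and their defaults, and
the design decisions taken where conventions genuinely differ. The
running example is the CLCF-SF, a 15-item caregiver-reported measure of
the challenge of living with a child with cystic fibrosis, reduced from a
46-item pool; the packaged definition (`clcf_sf()`) carries its published
structure — 13 five-point and 2 four-point items scored from 1, five core
items — with placeholder item wording.

## Item selection by genetic algorithm

A candidate short form is a subset of the item pool that must contain
every *core* item (items experts insist on). Its fitness is

$$\text{fitness}(S) \;=\; \alpha(S) \times \Big(1 - (k/K)^{d}\Big),$$

where $\alpha(S)$ is Cronbach's alpha of the subset, $k = |S|$, $K$ is
the pool size and $d \in \{2,3,4,5\}$ is the penalty order (default 3).
The two factors pull in opposite directions: alpha alone prefers to keep
every correlated item, while the penalty shrinks toward short forms. The
penalty's published rendering as a raw difference cannot lie in $[0,1]$,
so the package uses the ratio form above, which does and reproduces all
of the described behaviour (a subset of 15 from a pool of 46 at order 3
keeps a factor `ga_penalty(15, 46)` $\approx 0.965$ of its alpha); the
literal difference form remains available behind `variant = "raw"`
purely for audit.

The search itself (`ga_evolve()`) is a standard generational GA over
bitstrings on the non-core items: random initialisation, culling of the
worst half, uniform crossover between rank-sampled surviving parents,
per-bit mutation at rate $1/K$, elitism of one, and stopping once the
best fitness has not improved for 100 generations. Population size 200,
cull fraction 0.5 and the other defaults are conventional rather than
sacred: the exhaustive-search oracle in the test suite (all $2^{10}$
subsets of a 10-item non-core pool) is what guards correctness, and on
such pools the GA attains the global optimum. Ties between equal-fitness
subsets break deterministically toward fewer items, then lexicographic
item order. Candidate subsets may drop every non-core item; subsets with
fewer than two items are assigned fitness $-\infty$ rather than raising
mid-run. `ga_multi_start()` reruns the search from independently seeded
starting points (six by default) and reports whether all runs agree —
the practical check against local optima; on flat, all-noise landscapes
disagreement is reported, not raised.

Whether post-hoc "content validity" items should be locked in during the
search or appended afterwards is workflow-dependent; the package default
treats `core` as exactly the locked set, so appending afterwards is
simply a second call to `sum_score()` with the enlarged subset.

## Classical test theory

`cronbach_alpha()` implements
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_j s_j^2 / s_T^2\bigr)$
with $n-1$ variance denominators throughout (the convention matters in
small samples, so it is fixed and documented). Items with different
numbers of response options enter unrescaled, as is standard; a
standardized (correlation-based) variant is available.

Two confidence intervals are provided. The default is Bonett's: on the
$\log(1-\alpha)$ scale the estimator is approximately normal with
variance $2k/\{(k-1)(n-2)\}$, giving an interval that back-transforms to
$1-(1-\hat\alpha)e^{\pm z\,\mathrm{se}}$. The Feldt interval, from the
exact F distribution with $n-1$ and $(n-1)(k-1)$ degrees of freedom, is
available for comparison because published intervals for alpha are often
asymmetric and rarely state their construction. Simulation in the test
suite checks that the 95% Bonett interval covers a true alpha of 0.8 in
at least 93% of 1000 replications at $k=15$, $n=135$.

`alpha_if_deleted()` and `corrected_item_total()` are the usual item
diagnostics; item-total correlations below 0.20 (a common inclusion
guideline) are flagged. `scaled_mean_rating()` divides each item's mean
code by its option count so 4- and 5-point items can be compared on one
(0, 1] scale. `reliability_report()` assembles all of these into the
standard item table.

## Missing data

`impute_median()` replaces each missing cell by the item's median over
all supplied respondents (cohorts are pooled deliberately — the
imputation should reflect the sample actually analysed). With an even
number of observations the default is the *lower* median, so the imputed
value is always an attained ordinal code; the midpoint-rounded
alternative is an option because conventions differ and published
analyses rarely state theirs. Imputation is idempotent and never creates
out-of-range codes; the audit record (cells, missing fraction, medians
used) travels with the completed data.

## Factor structure from polychoric correlations

Ordinal items violate the linearity assumptions behind Pearson
correlations, so factor analysis proceeds from the polychoric matrix:
each pair of items is modelled as a discretised bivariate normal, with
thresholds estimated from the margins by the inverse normal and the
latent correlation maximising the cell likelihood (the standard two-step
estimator; joint estimation buys little at these sample sizes). The
bivariate-normal rectangle probabilities use a Gauss–Legendre evaluation
of the $\partial \Phi_2 / \partial \rho$ identity, accurate to ~1e-8
against an independent implementation. If the assembled matrix has a
negative eigenvalue it is smoothed to the nearest correlation matrix and
flagged; the raw matrix is kept alongside.

`efa_ml()` runs maximum-likelihood factor extraction on that matrix.
Because "the second eigenvalue" can mean either the correlation-matrix
eigenvalue or the second factor's sum of squared loadings, both are
reported; `check_unidimensionality()` applies the conventional rule —
second *correlation-matrix* eigenvalue strictly below 1 — and the strict
boundary means independent items (all eigenvalues exactly 1) fail, which
is the sensible reading for a scale that is supposed to share a factor.

## Rating Scale Model for treatment-management items

Treatment-management items ("how hard is this treatment to manage":
three ordered categories per treatment) are structurally missing
whenever a child does not receive a treatment. The Rating Scale Model
handles this naturally: with person trait $\theta$, item difficulty
$\beta_i$ and thresholds $\tau_1..\tau_{m-1}$ shared across items,

$$P(X_{pi}=c \mid \theta_p) \propto \exp\Big\{c(\theta_p-\beta_i) -
\sum_{l \le c}\tau_l\Big\}, \qquad c = 0,\dots,m-1,$$

and missing cells simply contribute nothing to the likelihood.
Estimation is marginal maximum likelihood by EM with a fixed grid of 41
quadrature nodes on $[-6, 6]$ weighted by the standard-normal density,
EM tolerance $10^{-5}$ on the log-likelihood and a cap of 500
iterations. The latent distribution is fixed at N(0,1) and —
because adding a constant to every difficulty while subtracting it from
every threshold leaves the likelihood unchanged — thresholds are
additionally constrained to sum to zero. (Conditional-ML Rasch software
instead centres the difficulties; estimates differ by a constant shift
only.) Standard errors come from the numerically evaluated observed
information of the item parameters, person scores are posterior means
(EAP) with posterior SDs, and maximum-likelihood scoring is deliberately
not the default since it diverges for extreme response patterns. Items
answered in only one category are inestimable and are excluded with a
warning rather than silently absorbed. The test suite checks the
dichotomous special case against an independent direct-optimisation
Rasch fit, EM monotonicity of the log-likelihood, and difficulty
recovery with and without 30% missing-by-design cells.

`compare_difficulties()` aligns two fits — e.g. caregiver-rated versus
child-rated management of the same treatments — and `autoplot()` draws
the classic paired difficulty plot with ±SE bars.

## Validity

Convergent validity (`cor_validity()`) follows the normality-gated
convention: Shapiro–Wilk on *both* variables, Pearson if both pass at
the 5% level, Spearman otherwise. The gate's outcome, both coefficients
and the rationale are always reported, so the choice is transparent and
reversible. Shapiro–Wilk is defined for at most 5000 observations; for
larger vectors a deterministic evenly spaced subsample is tested.
Discriminant validity (`known_groups_test()`) is the classical
pooled-variance independent t-test with the 95% CI of the mean
difference and Cohen's d from the pooled SD ($n-2$ denominator); Welch
is a flag because published "independent t-tests" rarely say which they
are, and the choice never affects the sign or the mean difference
itself. `validity_battery()` runs one comparison per external measure on
its own pairwise-complete cases — external covariates routinely differ
in availability — and leaves p-values unadjusted by default (the usual
reporting convention for validity batteries), with Holm available.

## Precision planning

`bonett_required_n()` inverts the Bonett interval: the smallest $n$
whose half-width on the alpha scale, $(1-\alpha)\sinh(z\,\mathrm{se})$,
meets the target. Planning "across 0.7–0.9" is evaluated at the smallest
alpha in the range because the interval is widest there. At $k=15$,
planning alpha 0.7 and a ±0.1 target the answer is 79 respondents, so a
cohort of 135 is comfortably sufficient — and `fisher_halfwidth()`
confirms such a cohort pins a correlation of 0.3–0.4 down to roughly
±0.14. A note on inputs: power percentages sometimes quoted alongside
such calculations have no role in a pure precision computation, which
involves only the planning value, the confidence level and the target
width.

## The synthetic cohort generator

`cohort_spec()`/`simulate_cohort()` generate the data every stage is
tested on. Ordinal responses discretise a one-factor model
($z_{ij} = \lambda_j\theta_i + \sqrt{1-\lambda_j^2}\,\epsilon_{ij}$,
standard-normal trait and noise) at per-item thresholds, which is
exactly the data-generating model the polychoric estimator assumes — so
polychoric and EFA recovery are exact-model tests. Missingness is
completely at random. Covariates are $\rho\,\tilde\theta +
\sqrt{1-\rho^2}\,\eta$ with $\tilde\theta$ the standardised trait, so
target correlations hold in expectation; binary groupings shift the
trait by a stated standardised amount.

Defaults encode the reference cohort: 135 respondents, loadings 0.5
(which put the 15-item alpha near 0.8), 1.6% missingness, covariate
correlations 0.48 / 0.41 / 0.43 / −0.37 and group shifts 0.37 and 0.26.
What the generator does *not* emulate: multidimensional minor factors,
informative missingness, cohort heterogeneity, skewed trait
distributions, or clinically realistic treatment mixes — so passing
recovery tests demonstrates correctness of the machinery under the
stated model, not robustness to real-data violations of it.

Two calibration notes on the round-trip tests. First, correlation and
effect-size recovery is checked against the *latent trait*, not the
ordinal total score: totals attenuate trait–covariate correlations by
roughly the square root of the reliability (~7% here), which is a
property of ordinal measurement, not an estimation error, and would
confound a ±0.04 recovery check of the generator and battery machinery.
Second, the planted-structure selection check uses 8 signal items with
loadings 0.4 among 12 pure-noise items at $n = 1000$: at these values
the population fitness of the full signal set exceeds its best
seven-item subset by about 3%, comfortably above sampling error, so the
optimum is unambiguous and six independent GA starts are expected to
agree on it exactly. With stronger loadings the cubic penalty can
genuinely prefer dropping a marginal signal item — a real property of
the alpha-times-penalty objective worth knowing when choosing the
penalty order.

## Problem sizes

The shipped checks run at the scales the workflow targets: exhaustive GA
verification on 10-item non-core pools ($2^{10}$ subsets, 20 datasets),
multi-start agreement on 20-item pools at $n=1000$, polychoric recovery
at $n=5000$, RSM recovery with 7 items at $n=2000$, unidimensionality
over 100 replications of 15 items at $n=1000$, and interval coverage
over 1000 replications at the reference cohort size. The full suite
completes in a couple of minutes on a single core.

## Limitations

Alpha-optimised selection capitalises on chance in the construction
sample, so the resulting short form's alpha is optimistic and needs
confirmation in an independent sample. The GA offers no optimality
guarantee beyond the multi-start agreement heuristic on pools too large
to enumerate. The RSM assumes equal discrimination across items and
shared thresholds; neither is tested here (no partial-credit or graded
alternatives, no differential item functioning). The polychoric
estimator assumes latent normality, which the generator satisfies by
construction but real data need not. Reliability here means internal
consistency only — no omega, no test–retest.
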
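---
title: "Models and methods: inhaler-preference discrete choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: inhaler-preference discrete choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery: the
random-utility model and its assumptions, the design criterion, what the
synthetic cohort does and does not emulate, the numerical choices, and the
known limitations. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The choice experiment

Each choice task shows a respondent two fictitious dry-powder inhalers
described by seven attributes (ease of use in 3 levels, dose-counter
accuracy, dose confirmation by lactose taste, mouthpiece hygiene in 3
levels, handling flexibility, usability during breathing difficulties, and
a monthly cost increment of 0/3/6/10 EUR over current expenditure), plus
the respondent's current inhaler. Choices are collected in two steps —
first between the two fictitious devices, then between that winner and the
current device. Because the model assigns each alternative a single utility
draw per task, the two steps together reveal the complete ranking of the
three alternatives: the step-2 winner is ranked first, and transitivity
orders the rest. `simulate_study()` constructs records this way and
`validate_choice_csv()` enforces exactly this consistency on import.

## Random-utility model

For alternative $j$ in a task answered by respondent $i$:

$$U_{ij} = x_j'\beta + c_j\,\beta_{cost} + \mathbf{1}[j = sq]\,(\delta + b_i) + \varepsilon_{ij},$$

with dummy-coded device attributes $x_j$ (reference levels: more than 4
steps, no accurate counter, no lactose taste, dry-cloth-only mouthpiece,
fixed-position handling, not usable during breathing difficulties), the
cost increment $c_j$ entered linearly in EUR/month, a status-quo constant
$\delta$ for the current inhaler, a patient effect
$b_i \sim N(0, \sigma^2)$, and independent standard Gumbel errors
$\varepsilon_{ij}$.

The patient effect sits on the status-quo constant only. In a conditional
logit, any term common to all alternatives in a task cancels out of the
choice probabilities; the only patient-constant term that survives
differencing is alternative-specific. Correlating the repeated status-quo
utilities is therefore the minimal placement that makes a respondent's
twelve answers dependent, which is the stated purpose of the random effect.
Normality is an assumption, not an identity; the distribution of the
original study's patient effect is unknown.

The probability of an observed ranking $r_1 \succ r_2 \succ r_3$ is the
exploded-logit product of MNL stages,

$$P(r \mid b) = \frac{e^{U_{r_1}}}{e^{U_{r_1}}+e^{U_{r_2}}+e^{U_{r_3}}}\cdot
               \frac{e^{U_{r_2}}}{e^{U_{r_2}}+e^{U_{r_3}}},$$

and the per-respondent likelihood integrates the product over tasks against
the $N(0,\sigma^2)$ density. These probabilities are location-invariant and
sum to one over the six rankings; both properties are asserted to 1e-12 in
the tests against a brute-force permutation oracle.

## Design generation

Designs are scored by D-efficiency, $\det(M)^{1/p}/n_{sets}$, where $M$ is
the MNL Fisher information accumulated over choice sets,
$M = \sum_s X_s'(P_s - p_s p_s')X_s$. Choices made where the design problem
was genuinely open:

* **Prior coefficients.** The information matrix is evaluated at
  $\beta = 0$ (utility-neutral design, all choice probabilities 1/2). No
  pilot estimates are available for design construction, and the
  main-effects dummy coding honours the no-interaction assumption.
* **Coding for design construction.** Dummy coding against the reference
  levels; cost by its numeric increment *centred* on the mean of its level
  set, so the cost column is orthogonal to an implicit intercept.
* **Search.** Profile-level coordinate exchange: every alternative of every
  set is offered all 576 candidate profiles in turn, with rank-one
  determinant updates (Sherman-Morrison) vectorised over candidates and an
  exact determinant check before accepting an exchange, so the search is
  monotone by construction. 20 random restarts, all seed-derived. Exchanges
  that tie the incumbent are rejected (stability).
* **Within-set overlap.** Two alternatives may share levels on some
  attributes; only fully identical profile pairs are forbidden.
* **Status quo.** The current inhaler varies per respondent and is unknown
  at design time, so it is excluded from design optimisation.
* **Blocking.** Sets are split into equal blocks, then greedily swapped to
  minimise the maximum per-block deviation of level frequencies from
  perfect balance (ties broken by the sum of squared deviations). With a
  continuous cost attribute, D-optimality concentrates cost on its extreme
  levels; the categorical attributes come out balanced to within +/-2 of
  the ideal frequency in the generated 36-set design, and the blocking
  criterion treats each cost value as a label.

The design module regenerates an instrument from the stated criteria; it
does not (and cannot) reproduce the original survey's actual sets, which
were never published.

## Synthetic cohort

`cohort_config()` defaults encode the published sample: 201 asthma and 93
COPD respondents; mean (SD) ages 40.30 (13.44) and 48.48 (15.16), normal,
rounded, floored at 18 (the floor shifts the asthma mean by under 0.3
years); female fractions 0.687/0.548; a 47/53 split between the two study
devices; the observed income-band frequencies; monthly out-of-pocket cost
as a Gamma matched to mean/SD 11.89/21.93 and 22.11/37.37 (nonnegative,
right-skewed, as cost data are); HUI3 as a Beta matched to 0.71/0.25 and
0.54/0.30 (bounded in [0,1]). Satisfaction is reported only as "52%/46%
satisfied"; the remainder is split 30/18 and 34/20 between neutral and
unsatisfied as a one-time realism choice. Covariates are drawn
independently within disease group — only marginals were published, so no
dependence structure is imposed.

The current inhalers' attribute descriptions were never tabulated in the
study. The defaults (`default_device_profiles()`) describe two plausible
devices — both 2-3 preparation steps, fixed orientation, dry-cloth
mouthpiece, unusable during breathing difficulties, with counter accuracy
and lactose taste differing by device, cost increment 0 — and are
configuration, not fact. What passing tests show is that the *estimator*
recovers the generating process at study scale; they cannot show that this
generating process equals the real survey population (no attrition, no
inattention, no covariate dependence, exact 12-task completion per
respondent is assumed).

Seeding: a master seed expands into per-respondent and per-(respondent,
task) substreams via a small integer-fold hash, so any record's draws are
reproducible regardless of simulation order, and exports are byte-identical
under a fixed seed.

## Estimation

* **Quadrature.** The patient effect is integrated by *non-adaptive*
  Gauss-Hermite quadrature, 15 nodes by default. The integrand — a product
  of twelve bounded stage probabilities against a normal density — is
  smooth and effectively single-moded at study-scale $\sigma$; 15 standard
  nodes agree with 41 nodes to below 1e-8 in log-likelihood on simulated
  data, so the per-respondent mode search of adaptive quadrature buys
  nothing here. A single node at zero reduces the likelihood *exactly* to
  the plain exploded logit, which the tests assert to 1e-10.
* **Scale of sigma.** $\sigma$ is estimated as $\log\sigma$ to keep it
  positive. On data generated with $\sigma = 0$ the estimate runs to the
  boundary; a fit is still declared converged when all utility-scale
  gradients are tight and $\sigma < 10^{-3}$, since the profile
  log-likelihood is flat in $\log\sigma$ there.
* **Optimisation.** BFGS with the analytic gradient (C++ core, shared by
  likelihood, gradient and MCMC), started at 0 for utilities, -0.05 for
  cost, $\sigma = 0.1$. Line searches stall once objective improvements
  reach the floating-point noise of a 2,400-term sum, so a Newton polish on
  the exact gradient (observed information recomputed at most twice)
  finishes the job; convergence means gradient norm below 1e-5. Standard
  errors come from the inverse observed information (central-difference
  Jacobian of the analytic gradient, relative step 1e-5).
* **Separation.** Utility estimates beyond +/-15 trigger a warning naming
  the column; SEs are withheld on non-converged fits.
* **Interactions.** Disease interactions multiply coded attribute columns
  by the COPD indicator; Wald block chi-squares per attribute plus a pooled
  LRT, with stratified fits recommended when any block is significant at
  0.05. Covariate x status-quo interactions code gender as a female
  indicator, age mean-centred, income as a 1-5 band score (respondents with
  "No answer" are dropped for that model, with a message), satisfaction as
  two dummies against unsatisfied (its interaction p is a 2-df block test).
  Raw p-values are reported without multiplicity correction, matching the
  study's reporting style.
* **Open readings.** "Ranked ordered logit" is read as the exploded
  three-alternative ranking likelihood (that is what the term denotes),
  rather than two separate binary models; the per-cell meaning of the
  covariate-interaction table in the original report is under-specified,
  so the table reproduces the layout with Wald p-values and this choice is
  documented rather than hidden.

## Willingness to pay

$WTP = \hat\beta_{term}/(-\hat\beta_{cost})$ EUR/month, invariant under
joint rescaling of the coefficients. Credibility intervals come from
random-walk Metropolis on the model log-likelihood with flat priors
(improper on coefficients, flat on $\log\sigma$), initialised at the MLE
with proposal covariance $(2.38/\sqrt{p})^2\,\hat V$; defaults 30,000
iterations, 5,000 burn-in, thinning 5, chosen for desk-scale runtime with
stable 2.5/97.5 percentiles. Acceptance rates outside [0.1, 0.6] trigger a
rescaling warning. Draws with a non-negative cost coefficient — where the
ratio is undefined — are excluded and counted (they are vanishingly rare at
study scale). The posterior *mean* is the headline summary ("expectation of
a statistic"); the MLE point ratio is reported alongside because a
posterior mean of a ratio sits above the ratio of means (Jensen), which the
tests verify against numeric integration.

## Problem sizes in the checks

The test suite and acceptance script size their simulations as follows:
parameter recovery uses 50 replicate studies of 201 respondents x 12 tasks
at the published asthma coefficients with $\sigma = 0.5$; the
disease-by-cost power check uses 100 replicates of the pooled 294-respondent
study with a targeted cost x disease interaction fit on a 9-node rule; WTP
interval coverage uses 100 replicate studies with shortened Metropolis
chains (1,200 iterations, 300 burn-in) on a 5-node rule — the wide coverage
band (90-99 of 100) absorbs the extra Monte-Carlo noise of the short
chains. Null-calibration checks run at reduced cohort sizes, where
uniformity of p-values holds just as it does at full scale.

## Known limitations

* The exploded-ranking likelihood conditions on complete, transitive
  rankings; partial rankings or "none" options are out of scope.
* One normal random effect on the status quo; no random coefficients on
  device attributes (mixed logit), no latent classes, no WTP-space
  estimation.
* D-efficiency at a zero prior only — no Bayesian design priors, no
  interaction-supporting or partial-profile designs.
* The synthetic cohort reproduces published marginals, not joint
  distributions or behavioural artefacts of real web-survey data.
* HUI3 is carried as an opaque covariate; the scoring algorithm is not
  implemented.
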
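---
title: "Simulating and decomposing a dual-frame targeted household survey design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decomposing a dual-frame targeted household survey design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualframe)
```

## The design being modelled

`dualframe` simulates and analyses the sample design used by the continuous
NZ Health Survey: a stratified multistage area sample supplemented by a list
sample from the Electoral Roll, built to deliver usable precision for
Māori, Pacific and Asian adults without giving up too much precision for
national estimates.

The pieces, in the order the sampler executes them:

1. **Stratification and allocation.** Strata are District Health Boards
   (21 of them, from roughly 30,000 to 460,000 people). The annual
   meshblock sample is allocated across strata proportionally to
   $\mathrm{population}^q$ with $q = \tfrac12$ by default — the power
   allocation that compromises between proportional allocation (best
   nationally) and equal allocation (best for small strata).

2. **Targeted PPS selection of meshblocks.** Within stratum $h$, meshblock
   $i$ is selected with probability
   $$\pi_i = m_h \, N^*_i f_i \Big/ \sum_{j \in h} N^*_j f_j,$$
   where $N^*_i$ is the meshblock's census dwelling count and $f_i$ a
   *targeting factor*
   $$f_i = 0.31\sqrt{p^{MB}_i} + 0.37\sqrt{p^{AU}_i} +
           0.09\sqrt{a^{MB}_i} + 0.20\sqrt{a^{AU}_i} + 0.03,$$
   with $p$ and $a$ the Pacific and Asian population densities at
   meshblock and area-unit level. Square roots keep the targeting "light"
   (over-targeting is known to backfire); the area-unit densities buffer
   against out-of-date census data. Any $\pi_i \ge 1$ is resolved by an
   iterative certainty treatment: such meshblocks are selected with
   probability exactly 1 and the remainder re-solved so the probabilities
   still sum to $m_h$.

3. **Households within meshblocks.** Households are taken at rate
   $c/N^*_i$, i.e. $H_i c / N^*_i$ of the $H_i$ dwellings present at
   enumeration, with $c = 20$ by default. We interpret $N^*_i$ as the
   census *dwelling* count: with it, an unchanged meshblock yields exactly
   $c$ households, and the product of the two stages makes the household
   selection probability proportional to $f_i$ within each stratum — the
   design's defining "lightly targeted" property. Fractional takes are
   resolved by stochastic rounding (floor plus a Bernoulli on the
   fraction), which keeps the expectation exact; deterministic rounding
   would bias the realized selection probabilities.

4. **The electoral-roll list frame.** Before the area draw, each stratum
   draws roll meshblocks with probability proportional to their number of
   Māori-descent addresses, then takes a simple random sample of up to 10
   such addresses per selected meshblock. Roll and area meshblock sets are
   constrained to be disjoint: roll meshblocks are removed from the area
   frame and the area probabilities renormalized. The number of roll
   meshblocks per stratum is sized from the frame so that the roll supplies
   the configured share (15% by default) of responding households — the
   PPS-expected address take per selected meshblock,
   $\sum_i R_i \min(10, R_i) / \sum_i R_i$, converts the household target
   into a meshblock count.

5. **Within households.** One adult (15+) and one child (0–14, if any) are
   selected uniformly at random, without reference to the Roll, so
   within-household probabilities are exactly $1/\#\text{adults}$ and
   $1/\#\text{children}$ and Māori members are not preferentially selected.

6. **Quarters.** Selected meshblocks (both frames) are dealt at random to
   quarters, balanced within stratum, so each quarter is itself a
   probability sample.

## Pooled inclusion probabilities

Weights are inverse probabilities of being in the *pooled* sample. Writing
$S$ for the (random) set of roll meshblocks in a household's stratum, the
household's pooled probability is

$$P(\text{hh}) = \mathbf{1}\{\text{roll-flagged}\}\,\pi^{roll}_i
  \frac{\min(k, R_i)}{R_i}
  + \mathbb{E}_S\!\left[\mathbf{1}\{i \notin S\}\, \pi^{area}_i(S)\right]
  \frac{c}{N^*_i},$$

because households in roll-selected meshblocks can only enter through the
roll. The expectation over $S$ is the non-trivial part. We compute it
exactly when a stratum draws at most one roll meshblock — the sample space
is then the singletons $\{j\}$ with $P(\{j\}) = \pi^{roll}_j$ — and by
Monte-Carlo conditioning (default 2,000 simulated roll draws) otherwise.
Randomized-order systematic PPS has no closed-form joint sample
probabilities for two or more draws, which is why no exact enumeration is
attempted there. Both routes depend only on the frame and the design, so
the probabilities are computed once and reused across replicate draws.

One consequence worth knowing: a meshblock whose roll probability reaches 1
is *never* available to the area frame, so its non-roll households are
uncovered (probability zero). The probability calculator reports how many
people this affects; at realistic scales it is a fraction of a percent, and
the Horvitz–Thompson identities hold for the covered population.

## Estimation

* **Prevalences** use the Hájek (ratio) estimator — weighted mean with the
  weighted count in the denominator — restricted to the subpopulation's
  respondents. Indicator machinery runs on adults (15+).
* **Variances** come from a delete-a-group jackknife over meshblocks
  (the PSUs of both frames): PSUs are randomly spread over $G = 100$
  groups within strata; replicate $g$ zeroes its PSUs and rescales the
  remaining weights within each stratum by the ratio of full to remaining
  stratum weight, so every replicate reproduces the stratum weighted
  totals exactly; the variance is $(G-1)/G \sum_g (\hat\theta_g -
  \hat\theta)^2$. With $G$ equal to the number of PSUs this is the
  delete-one jackknife. Strata with a single PSU contribute no variance
  and are reported.
* **Design effects** divide the estimated variance by the binomial
  variance $p(1-p)/n_{sub}$ of an SRS of the same size.
* **ICCs** use the one-way ANOVA estimator with the unequal-group-size
  adjustment $k_0 = (N - \sum n_i^2/N)/(a-1)$, clipped to $[0, 1]$.
* **Response rates** follow the RR3 convention: interviews over
  interviews + eligible non-interviews + an estimated-eligible share $e$
  of unknown-eligibility cases, $e$ defaulting to the eligibility rate
  among resolved cases.

## The design-effect decomposition

Kish's approximation for unequal-weight, unclustered designs,
$\mathrm{var}(\hat{\bar Y}) \approx (1 + C_w^2)\, S^2_Y / n$, extends to a
four-design ladder, all normalised to the same total person sample size:
(a) SRS of persons; (b) stratified SRS of persons under the power
allocation; (c) stratified SRS of households with one adult each; (d) the
actual design. The design effect for a subpopulation then factorises into a
weight-variation term $(1+C^2_{new})/(1+C^2_{old})$ and an
over/undersampling term $n_{old}/n_{new}$ for each rung, and each factor is
estimable from the realized design-(d) sample alone:
$$\hat n_{sub}(x) = \sum_{s_d \cap sub} w_{di}\, \pi_{xi}, \qquad
  1 + \hat C^2_{sub}(x) = \frac{\sum w_{di} \pi_{xi} \,
  \sum w_{di} \pi_{xi}^{-1}}{\left(\sum w_{di}\right)^2}.$$
The counterfactual probabilities come from frame summaries: $\pi_a = n/N$;
$\pi_b = n_h/N_h$; $\pi_c = (n_h / H^+_h)(1/\text{adults in household})$
with $H^+_h$ the stratum's count of households containing adults; $\pi_d$
is the realized pooled probability. The weighted sums in
$\hat n_{sub}(x)$ are restricted to subpopulation respondents (the
subpopulation restriction is implicit in the estimator's derivation). By
Cauchy–Schwarz the $1+\hat C^2$ estimator is never below 1, with equality
exactly when $\pi_{xi}$ is constant over the subpopulation sample.

The product of the last two factors (rows *e* and *f* of the component
table) measures the net effect of within-stratum targeting plus the dual
frame; `summarize_variance_change()` converts it to a percent variance
change. `published_deff_components()` carries the component table reported
for the survey's first year as a worked example; its Pacific product row
(0.74) differs from the rounded product of its printed factors (0.73)
because the published row was computed from unrounded intermediates, and it
is kept as printed.

Comparisons of the six-row product against realized design effects use the
ladder's own convention: the SRS baseline variance for a subpopulation is
$p(1-p)/(n \times \text{population share})$ — design (a) at the *same
total* $n$ — not the realized subpopulation sample size, which design (d)
deliberately inflates.

## The synthetic population

The generator reproduces the structural features the design exploits; all
defaults are fixed, and scaling (`total_persons`) shrinks stratum sizes
while leaving meshblock and household structure untouched.

* **Strata**: person targets log-spaced over 30,000–460,000 (times the
  scale factor).
* **Meshblocks**: lognormal household counts, mean 40, CV 70%. The
  lognormal form is a modelling choice; only the mean and CV are given by
  the design documentation.
* **Area units**: 20 meshblocks each (≈ 800 dwellings).
* **Ethnic densities**: a two-level logit-normal latent field — an
  area-unit component plus meshblock-level jitter, both carrying the same
  latent correlation matrix. We use correlated logit-scale jitter rather
  than an independent beta jitter because independent jitter both
  attenuates and destabilises the meshblock-level cross-ethnicity density
  correlations the generator is asked to reproduce (Asian–Pacific +0.14,
  Asian–Māori −0.15; the unobserved Māori–Pacific pair is set to +0.30 as
  a realistic co-location value). Latent correlations are inflated by a
  factor 1.3, calibrated once against large simulated fields, to undo the
  logit attenuation; the area-unit component carries 30% of the latent
  variance. If a configuration cannot achieve its targets (e.g. near-zero
  prevalences) the achieved correlations are reported in a warning.
* **Households**: ethnicity flags are Bernoulli draws from the meshblock
  densities; household size is 1 + Poisson with an ethnicity-dependent
  mean (2.5 baseline; 3.0/3.6/3.1 for Māori/Pacific/Asian households).
  The size gradient is what makes one-per-household sampling undersample
  Pacific and Asian people, so that row (d) of the decomposition emerges
  from structure rather than assumption. Members inherit the household's
  flags; person-level prevalence targets are met by deflating the
  household-level density target by the size ratio.
* **Persons**: the first member is always an adult; further members are
  adults with probability 0.65, giving the ~78/22 adult/child split.
* **Electoral roll**: Māori-descent is the Māori ethnicity flag plus a 5%
  descent-without-ethnicity rate among other adults (descent is a broader
  concept than total-response ethnicity); 80% of descent adults are
  enrolled at their address. Both rates are configurable; the 80%
  reflects the known imperfect coverage of list-based Māori
  identification.
* **Outcomes**: binary indicators generated from meshblock-level
  beta-distributed prevalences with mean $p$ and variance
  $\rho\,p(1-p)$, so the within-meshblock ICC equals $\rho$ by
  construction; optional per-ethnicity log-odds shifts create
  subpopulation contrast. Defaults mirror three typical adult indicators
  (prevalence/ICC 0.544/0.21, 0.442/0.06, 0.184/0.04 with Māori and
  Pacific smoking shifts).
* **Census drift**: `census_snapshot(pop, drift)` perturbs current
  dwelling counts around the census values with mean relative change
  `drift` (normal multiplicative noise, scaled so
  $\mathbb{E}|\Delta|/H = $ `drift`), while census counts and densities
  stay at their generation-time values. Drift affects within-meshblock
  take sizes — the efficiency channel the design documentation worries
  about — not the household roster itself.

What the generator does *not* model: real geography and migration,
interviewer effects, call-backs, institutional (rest-home) populations,
seasonal behaviour, or informative nonresponse (nonresponse is independent
Bernoulli per household, optionally ethnicity-dependent, and is folded into
the probabilities so base weights stay unbiased under it). Passing tests on
this population demonstrate internal statistical correctness of the design
machinery — probabilities, weights, variance estimators, decompositions —
not fidelity to any real survey's point estimates.

## Choosing targeting coefficients

The original coefficients were obtained by numerical optimisation against
historical survey and census data, which a synthetic-frame study does not
have. `optimize_coefficients()` therefore minimises an *anticipated
variance* objective built from the Kish model: for each subpopulation, the
frame-level probabilities induced by a candidate coefficient vector give
$(1 + C^2_{sub})/n_{sub} \cdot p(1-p)$, and the objective is an
importance-weighted sum. The proxy uses the area frame only (the
coefficients steer the area component; the roll is a fixed Māori-specific
overlay), and no clustering penalty enters by default. Coefficients are
constrained to the unit simplex — the published values sum to 1.00 — and
the search is Nelder–Mead on a softmax parameterisation with multiple
seeded starts. Anticipated-variance reductions on this surrogate should be
read as directional, not as predictions of field performance.

## Numerical and scale choices

* Simulation sizes used by the test-suite: a ~50,000-person NZ-like
  population (about 500 meshblocks, 21 strata) with 1,500 responding
  households per annual draw for distributional checks; a two-stratum
  micro-population of a couple of dozen households for exact probability
  checks (its strata draw at most one roll meshblock each, so pooled
  probabilities are exact); 500 replicate draws for unbiasedness and
  realized-variance comparisons; $10^5$ replicate draws for per-person
  frequency validation.
* All randomness flows from one master seed through named, hashed
  substreams per stage (structure, densities, households, persons, roll,
  each draw's stages, jackknife grouping), so any stage can be re-run in
  isolation and experiments are bit-reproducible.
* Degenerate inputs: zero prevalences yield empty flags and a roll-less
  design; strata without roll addresses fall back to area-only sampling
  (reported); meshblock takes are capped at the dwellings present;
  certainty meshblocks are handled by the iterative peel in both frames;
  ICC estimates are clipped to $[0,1]$; design effects are undefined at
  prevalence 0 or 1 and reported as missing.

## Known limitations

* At small scales the roll frame occupies a much larger *fraction* of
  meshblocks than in the full-size design, so roll-driven weight variation
  is relatively stronger; directional conclusions survive scaling, exact
  component magnitudes do not.
* Households are ethnically homogeneous (members inherit household flags),
  which slightly overstates the roll's efficiency at finding Māori
  respondents; the descent-without-ethnicity rate counteracts this.
* The exact pooled-probability route requires at most one roll meshblock
  per stratum; beyond that the Monte-Carlo conditioning error is
  $O(1/\sqrt{n_{mc}})$ and folded into weights.
* The published component table's exact entries require the real survey
  microdata; the package reproduces the table's structure, internal
  identities and qualitative pattern on synthetic populations, plus the
  published worked example verbatim.
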
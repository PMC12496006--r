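---
title: "Modelling CT screening for lung cancer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CT screening for lung cancer: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscreen)
```

## What the package models

`lcscreen` is a microsimulation of lung-cancer natural history and low-dose
CT screening in the style of the NELSON trial: a four-round CT protocol
(years 0, 1, 3 and 5.5 from randomization) offered to high-risk current and
recent-former smokers aged 50--74, with an unscreened control arm and at
least ten years of follow-up. Each simulated person carries a complete life
history -- smoking exposure, lung-cancer onset, preclinical stage
progression, clinical diagnosis, post-diagnosis survival, screening events
and other-cause death -- and trial-level outcomes are aggregates over many
such histories. The quantities of scientific interest are the stage- and
histology-specific CT sensitivity (including the higher repeat-screen
sensitivity that volume-doubling-time information makes possible), the
stage IA sojourn-time distribution, and the stage-specific probability that
screen-detection prevents a lung-cancer death.

Individual-level data from the actual trial are restricted, so the package
ships a synthetic cohort generator that emulates the trial's eligibility
rules and size (12,474 men and 2,382 women), and the fitted parameter
tables are supplied as plain-text configuration. Everything downstream of
the generator is exercised exactly as it would be with real microdata.

## Natural history

**Onset.** Carcinogenesis follows the two-stage clonal expansion (TSCE)
model: normal cells are initiated at rate $\nu$, initiated cells divide at
rate $\alpha$, die at rate $\beta$, and convert to malignancy at rate
$\mu$. Smoking acts multiplicatively on initiation and on the net
proliferation rate $g = \alpha - \beta - \mu$ through
$x = x_0\,(1 + c\,\mathrm{cpd}^{\,p})$. Because only rate combinations are
identifiable, $\alpha$ is held fixed and $\beta$ is derived. For
piecewise-constant exposure the survival function has an exact closed form:
the probability $w$ that an initiated cell spawns no malignant descendant
solves a Riccati equation whose constant-coefficient solution is applied
segment by segment, walking backwards from the evaluation age. This closed
form (implemented in C++) is validated in the test suite against an
independent ODE integration of the same backward system. The onset age is
drawn by inverting the cumulative hazard at an exponential deviate,
interpolating on a half-year age grid; the constant-hazard special case
reduces exactly to an exponential draw, which is the sampler's oracle test.

**Progression.** From onset the cancer enters preclinical stage IA and
moves through IB, II, IIIA, IIIB, IV, spending a Weibull-distributed
sojourn time in each stage, specific to stage, histology (adenocarcinoma,
squamous, other NSCLC, SCLC) and sex. Sojourn distributions are
parameterized by mean and shape; the scale is recovered as
$\lambda = m/\Gamma(1+1/k)$. The fitted stage IA adenocarcinoma values
(mean 3.56 y for men, 4.77 y for women, shape 0.35) imply a heavy-tailed
distribution whose many short draws effectively let fast cancers skip
stages. At the end of each stage's sojourn, a Bernoulli draw with the
stage-specific clinical-detection probability decides between symptomatic
diagnosis and silent progression; stage IV always ends in diagnosis, so the
stage-at-diagnosis distribution is a sequential-Bernoulli product that the
tests check in closed form.

**Survival and competing mortality.** Post-diagnosis survival is
mixture-cure exponential per stage and histology: with the cure fraction no
lung-cancer death is scheduled, otherwise an exponential survival time is
added to the diagnosis age. The published description of the survival step
is ambiguous about the distributional family; mixture-cure exponential is
the minimal model consistent with "a survival time is drawn" plus long-term
survivors, and is flagged here as a design choice. Other-cause mortality
comes from a Gompertz--Makeham life table per sex (a configurable stand-in
for national statistics tables, which are not redistributed), adjusted per
person by $\exp(\gamma\,\mathrm{packyears}/40)$ with $\gamma = \log 2$
doubling other-cause mortality at 40 pack-years. The observed death is the
earlier of the lung-cancer and other-cause deaths.

## Screening mechanics

At each round a person contributes a screen only when attending, alive and
not yet diagnosed. A preclinical cancer (onset at or before the screen,
clinical diagnosis after it) is detected with the CT sensitivity of the
stage occupied at the screen instant ([sensitivity()]); stage entry
intervals are half-open. A *repeat* screen is any screen after the person's
first attended screen -- someone who missed round 1 gets baseline
sensitivity at round 2, because the repeat-screen advantage reflects
volume-doubling-time information that requires a prior scan. In parametric
mode the repeat boost is a per-histology logit shift $\beta_h \ge 0$, so
$\beta_h = 0$ makes repeat and baseline screens exactly equal (as fitted
for squamous, SCLC and other NSCLC); in table mode the fitted baseline and
repeat probabilities are used directly. Screen-detected persons leave the
screening pool but remain in mortality follow-up.

Upon detection, a lung-cancer death scheduled in the no-screening
counterfactual is cancelled with the stage-specific mortality-prevention
probability (0.83 for stage IA/IB in the fitted model); an unsuccessful
draw leaves the life history exactly as without screening, and a detection
whose counterfactual had no diagnosis before death is bookkept as
overdiagnosis. Setting all prevention probabilities to zero therefore moves
diagnoses but no deaths -- an invariant the test suite checks both exactly
(per person) and statistically (between arms).

The *all-screen average* sensitivity reported in the output tables is total
detected over total detectable across the four rounds, where the detectable
pool counts every screened person carrying a preclinical cancer of that
stage and histology at the screen instant, round by round.

## Synthetic cohort and life tables

The generator emulates the trial's eligibility rules -- more than 15
cigarettes/day for over 25 years or more than 10 for over 30 years, and
current smoking or quitting within the last 10 years -- by rejection
sampling (capped at 1,000 redraws per person, after which the configuration
is reported infeasible). Covariate distributions are configurable and
deliberately simple: age truncated-normal around 58 on [50, 74], integer
start ages near 17, a five-point cigarettes/day mixture, a 55:45
current:former split with quit times uniform within the last decade, and a
single-segment smoking history per person. Arms alternate deterministically
by id, removing one source of between-arm noise. The TSCE defaults were
chosen once so that a never-smoker's lifetime risk stays under one percent,
long-term heavy smokers carry a many-fold excess, and about 6 percent of
the cohort develops lung cancer within trial follow-up, matching the
trial's descriptive share. What the generator does *not* emulate: the joint
covariate structure of the real baseline population, multi-segment smoking
careers, birth-cohort trends in background risk, and calendar-time effects.
Passing tests therefore demonstrate the correctness of the machinery and
the internal consistency of the model, not agreement with restricted trial
microdata.

## Calibration

Simulated outcomes are compared to count targets through a composite
log-likelihood with equally weighted blocks (the published analysis states
no block weighting, so equal weights are assumed): Poisson terms for yearly
control-arm incidence and for interval cancers; one multinomial term per
round across negative screens and stage-specific positive screens; and
Poisson terms for lung-cancer deaths after screen detection with
person-year offsets. Simulated counts are scaled to expectations at the
observed size, treating the replication factor purely as a
variance-reduction device. A simulated expectation of zero against a
positive observation returns a large negative sentinel standing in for
$-\infty$.

Search uses the classic DE/rand/1/bin differential evolution scheme
(defaults $NP = 10\times$dimension, $F = 0.5$, $CR = 0.9$, 300 generations,
early stop after 50 stagnant generations), with probabilities searched on
the logit scale and positive quantities on the log scale. Every candidate
is evaluated with one frozen simulation seed (common random numbers), and
the trial engine pre-commits every random stream with parameter-independent
draw counts, so the objective is a smooth quasi-deterministic function of
the parameters and DE's monotone convergence is preserved.

Feasible ranges are profile-likelihood intervals: one parameter is walked
up and down on its transformed scale, holding the others fixed, until
$2(\hat\ell - \ell)$ crosses the 97.5th percentile of $\chi^2_1$ (5.024;
the published analysis does not state the degrees of freedom, and one is
the natural choice for single-parameter profiles), with linear
interpolation between bracketing grid points and explicit flags when a
bound is reached without a crossing. Whether to profile on the natural or
transformed scale was also open; the walk is on the transformed scale with
natural-scale reporting. The Poisson special case reproduces the
closed-form likelihood-ratio interval to well under one percent, which is
the machinery's oracle test.

## Problem sizes and numerical choices

The test suite validates distributional properties at $10^5$--$10^6$ draws
(three Monte-Carlo standard errors), runs the null-screening equivalence
check on a 100,000-person cohort, and performs parameter recovery on
targets from a 50-fold replicated trial-size cohort evaluated against a
25-fold replicated one, with a reduced DE budget ($NP = 10$, 16
generations). These sizes were chosen so the whole suite completes in
minutes while keeping Monte-Carlo error well inside every tolerance; the
recovery experiment's information content corresponds to several trials'
worth of data, which is what a $\pm 6$ percentage-point check on a single
experiment requires. Age grids use half-year resolution for hazard
inversion (exact for the piecewise-linear cumulative hazards of the
constant-hazard oracle); life tables close at age 110 with certain death;
stage-entry ties at screen instants resolve by the half-open convention;
and hazard evaluation uses a central difference with a $5\times10^{-4}$
year step.

## Known limitations

Sojourn parameters outside stage IA adenocarcinoma, cure probabilities
beyond stage IA/IB, clinical-detection probabilities, survival parameters
and the histology mix are synthetic stand-ins (plausible values, clearly
marked in the documentation) because the corresponding fitted tables are
not published in full. Stage imputation for cancers of unknown stage,
nodule-level volume-doubling-time modelling, false-positive/specificity
accounting and second primaries are out of scope; SCLC early-stage
sensitivities carry reference values from the earlier NLST fit, as no such
cancers were observed. Re-detection of a person after a positive screen is
not modelled (screen-detected persons exit the pool), which matches the
yield-accounting convention adopted here.
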
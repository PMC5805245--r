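---
title: "Modelling nutritional-stage dynamics by age and socioeconomic status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nutritional-stage dynamics by age and socioeconomic status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutridyn)
```

## The model

`nutridyn` implements a population-level stock-and-flow model of body mass
index (BMI) category dynamics. The population aged 0–59 is divided into
twelve 5-year age groups, each split into three stocks — *not overweight*
(N), *overweight* (W) and *obese* (O) — forming an aging chain: people
enter the first group as births, mature from group to group, and exit the
system at age 60. Within each group $i$ the categories exchange people at
four annual transference rates (TRs):

* $\tau_{1,i}$: not overweight → overweight,
* $\tau_{2,i}$: overweight → obese,
* $\tau_{3,i}$: obese → overweight,
* $\tau_{4,i}$: overweight → not overweight,

with retention rates $\alpha_{1,i} = 1-\tau_{1,i}$,
$\alpha_{2,i} = 1-\tau_{2,i}-\tau_{4,i}$, $\alpha_{3,i} = 1-\tau_{3,i}$,
so feasibility requires every rate in $[0,1]$ and
$\tau_{2,i}+\tau_{4,i}\le 1$. For the first group,

$$\frac{dN_0}{dt} = B_N + \tau_{4,0}W_0 - \tau_{1,0}N_0 - E_0^N,$$

and analogously for $W_0$, $O_0$; later groups replace births by the
maturation inflow $E_{i-1}^c S_{i-1}$. Births split the fertility outflow
of the childbearing-age population (ages 15–49, groups 3–9) across
categories:

$$B_c = \mu\,\theta_c\,\frac{f(t)}{Y_F-Y_I+1}
        \sum_{i=3}^{9}(N_i+W_i+O_i),$$

with $\mu$ the female fraction of that population, $f(t)$ the fertility
rate (children per woman, looked up piecewise-constant by calendar year,
no extrapolation), $\theta$ the birth fractions by category and
$Y_F-Y_I+1 = 35$ childbearing years. The survival fraction per 5-year
residence is $S_i = e^{-R_i Y}$ for a per-year mortality rate $R_i$; a
fraction $S_i$ of each exit matures into the next group and $1-S_i$ dies.
Mortality is the same across BMI categories within a group (no
category-specific excess mortality), net migration is zero, and
socioeconomic strata never exchange people.

### Exit-rate formulation

Two formulations of the exit rates are provided. The default,
`stock_outflow`, is the standard first-order aging chain
$E_i^c = \text{stock}_i^c/Y$ with $Y = 5$ years of residence: exits are
proportional to the stock, the chain drains under extreme conditions, and
the people ledger closes exactly. The alternative `literal_paper`
formulation defines each exit rate recursively as the group's *net inflow*
divided by $Y$. Under it an empty inflow implies zero exit regardless of
the stock, so a chain with no births never drains; it is retained behind a
flag for fidelity experiments only, and the default is used everywhere
else. Likewise the survival fraction is implemented with the negative
exponent (a positive one would exceed 1 for positive mortality), and the
births factor divides by the 35 childbearing years (multiplying would give
births the wrong dimension).

### Numerical integration

Integration is fixed-step Euler with `dt = 0.25` years by default —
matching the fixed-step system-dynamics engines this class of model is
usually run on — with classical RK4 available. Report points are integer
years. After each step, stocks are clamped at zero and the number of
clamped excursions is reported (none occur at the default step with
feasible inputs). Halving the step changes yearly prevalences by less than
$10^{-3}$ on the bundled full-horizon runs, and Euler at `dt = 0.01`
agrees with RK4 at `dt = 0.25` to the same tolerance. Because all flows
are linear in the stocks, scaling the initial population scales all
trajectories; prevalences are invariant.

## Estimating transference rates from two survey waves

The TRs are not observable directly: the input data are two
cross-sectional prevalence surveys five years apart (emulating the 2005
and 2010 ENDS waves), giving prevalences by single year of age 0–64. The
estimation heuristic treats the cohort aged $a$ at wave 1 as the same
people aged $a+5$ at wave 2. For each age group the one-year transition
matrix in category order (N, W, O), columns = source,

$$A_i = \begin{pmatrix}
1-\tau_{1,i} & \tau_{4,i} & 0\\
\tau_{1,i} & 1-\tau_{2,i}-\tau_{4,i} & \tau_{3,i}\\
0 & \tau_{2,i} & 1-\tau_{3,i}
\end{pmatrix}$$

is column-stochastic by construction, and $B_i = A_i^5$ projects each of
the group's five wave-1 single-age prevalence columns $P_{i,j}$ onto the
cohort's wave-2 ages. The rates minimize

$$CD_i = \sum_{j=1}^{5}\left\lVert P^{obs}_{i+1,j} - B_i P_{i,j}
\right\rVert_2^2$$

subject to the box and simplex constraints above. The twelfth group
(55–59) is fitted against the wave-2 ages 60–64, which is why wave 2 must
reach age 64 even though the simulation itself stops at 59.

### Optimization

The objective is a degree-10 polynomial in four bounded parameters.
`estimate_trs()` runs a multi-start local search: Latin-hypercube starts
over the feasible box (half of them shrunk toward the small-rate region
where annual TRs live), L-BFGS-B with exact analytic gradients obtained by
the product rule through the fifth matrix power, and a final
Levenberg–Marquardt polish with the analytic Jacobian. The polish matters:
for weakly identified groups the least-squares valley is so flat that
quasi-Newton steps stall around $10^{-11}$ above the floor, whereas LM
reaches it (noiseless recovery error $\sim 10^{-14}$). Ties in the
objective within `tol` are broken toward the smallest $\lVert\tau\rVert_2$,
making results deterministic under the seed. The joint constraint
$\tau_2+\tau_4\le 1$ is enforced by a quadratic penalty (it never binds at
realistic rates) and checked on the returned solution.

### Identifiability, honestly

Within one age group the data are five prevalence columns on the
2-simplex. What pins down the four rates is the *variation* of those
columns across the band: a band whose five columns are identical
identifies only the net flows ($\tau_1 N - \tau_4 W$ and
$\tau_2 W - \tau_3 O$), not the gross rates. With the obese stock at only
1.5–15% of a group, $\tau_2$ and $\tau_3$ trade off along a near-flat
ridge of the objective. At zero noise the minimum is still exact and the
estimator recovers generating rates to $10^{-4}$ and far better; under
survey-scale noise (prevalence sd 0.005) the global least-squares minimum
slides along that ridge, and recovery errors concentrate on $\tau_3$ (and
to a lesser degree $\tau_2$) with median errors of order $10^{-2}$, not
$10^{-3}$. This is a property of the estimation problem, not of the
optimizer — the lattice oracle in the test suite confirms the optimizer
attains the least-squares minimum. It also suggests that reported
obese-to-overweight rates of order $10^{-8}$ obtained by local
minimization on such data should be read as "indistinguishable from zero",
not as estimates with eight digits of meaning. Consumers of noisy-data
estimates should treat $\tau_1$ as well identified, $\tau_2$ as usable,
and $\tau_3$, $\tau_4$ as qualitative.

## The synthetic-survey generator

`generate_truth()` draws a ground-truth TR table per stratum. The
`paper_like` profile mirrors the magnitudes of the bundled reference
estimates: adult $\tau_1 \in [0.005, 0.04]$, $\tau_2 \in [0.002, 0.017]$,
adult recovery rates essentially zero, and recovery flows
($\tau_3, \tau_4$ up to 0.04) concentrated in the three childhood groups.
`random_feasible` draws uniformly over the feasible box.
`generate_waves()` then builds wave 1 from a smooth baseline age profile
and wave 2 by applying each group's $A_i^5$ to the wave-1 columns — the
exact process the estimator inverts, so at zero noise the objective is
zero at the truth. Optional Gaussian noise (default sd 0.005, the scale of
sampling error in a large household survey) is added to both waves, then
clipped at zero and renormalized to the simplex.

The baseline profile is a logistic ramp plus a small linear tilt per
category (overweight $0.05 + 0.002a + 0.34\,\sigma((a-26)/6)$; obese
$0.015 + 0.0015a + 0.15\,\sigma((a-34)/7)$), reaching adult levels around
45% overweight and 20% obese. The tilt keeps a non-zero age gradient
inside every 5-year band, which the estimator needs (see above). The
accompanying `synthetic_demography()` emulates an urban population of a
middle-income country around 2005: group populations declining from 3.1 to
1.1 million with age, a J-shaped mortality schedule (0.4% per year in
infancy, 0.04% at school age, rising to 0.8% at 55–59), fertility
declining from 2.1 to 1.8 children per woman over 2005–2030, female
fraction $\mu = 0.523$, and birth-category fractions
$\theta = (0.93, 0.05, 0.02)$. What the generator does *not* emulate:
survey design effects (clustering, weighting), age heaping,
cohort-specific secular trends, or measurement error correlated within
households — so green recovery tests certify the inverse machinery, not
robustness to every artefact of real survey data.

## Stratified runs, the prevalence ratio, and scenarios

`run_stratified()` runs the three socioeconomic strata (wealth-index
quintiles 1–2, 3 and 4–5) as independent chains on a shared calendar;
pooled outputs are count-aggregated, so pooled prevalence is the
population-weighted mean of the strata. The obesity prevalence ratio

$$PR(t) = \frac{\sum_{i=4}^{11} O_{i,\text{lower}}}
               {\sum_{i=4}^{11}(N+W+O)_{i,\text{lower}}} \Big/
          \frac{\sum_{i=4}^{11} O_{i,\text{higher}}}
               {\sum_{i=4}^{11}(N+W+O)_{i,\text{higher}}}$$

compares adult (20–59) obesity between the lower and higher strata;
$PR>1$ places the burden with the lower stratum. (The denominator uses the
higher-stratum obese stock throughout; a printed rendering of this ratio
elsewhere mixes a lower-stratum term into it, which would not measure
anything coherent.)

Policy scenarios are timed TR overrides with floor semantics: "raise
$\tau_3$ and $\tau_4$ to 0.02 for school ages during 2011–2030" sets the
effective rate to $\max(\text{baseline}, 0.02)$ inside the window and
leaves the baseline untouched outside it. A replace semantics would let an
intervention *lower* an already-better baseline rate, which is not what
"increase to" means. `compare_projections()` reports both the
prevalence-point difference and the relative change in percent, because
"decreased by 9%" is ambiguous between them; the relative reading is the
headline (it is the one consistent with paired prevalence values like
20.5 → 18.8).

## Bundled reference inputs and the 2005 reconstruction

`reference_tr_table()` ships the published TR estimates for the urban
Colombian population (ENDS 2005/2010), unstratified and by SES, as
plain-CSV fixtures; `mean_tr()` reproduces their per-stratum summary
statistics (e.g. lower-SES mean $\tau_1 = 0.0216$, mean
$\tau_2 = 0.0098$). The full-horizon projections those estimates were
published with, however, start from inputs that are not redistributable
here (single-age survey prevalences and official demographic tables).
`colombia_synthetic_inputs()` is therefore an explicitly *synthetic*
reconstruction: published 2005 aggregates anchor the age profile where
they exist (per-group adult prevalences for ages 15–39, pooled adult
overweight/obesity of 34.2%/15.7%, per-SES adult aggregates), childhood
and early-adult gaps take plausible survey-scale values, and the two
oldest adult bands are solved so the pooled adult aggregates hold exactly
under the synthetic age structure. Projections from this reconstruction
reproduce the *direction and rough magnitude* of the published 2030
figures (and the prevalence-ratio crossing near 2018) but not their exact
values; the acceptance suite asserts the published values anyway and
reports the differences rather than hiding them.

## Problem sizes and tolerances used by the test suite

The suite runs entirely on synthetic inputs built in code: 12-group
chains over 10–25-year horizons at `dt = 0.25` (one 200-year run for the
birth-fraction limit), estimator checks over 12 groups × 3 strata
noiseless plus 100 seeded noisy replicates at 4 restarts, and a 4-D
grid-search oracle on a 0.001-step lattice over $[0, 0.02]^4$ (21⁴ points)
for three randomly chosen groups. Conservation is checked to $10^{-6}$
relative (it holds to $10^{-14}$), solver agreement and step-halving to
$10^{-3}$ absolute on prevalences, stochastic-matrix closure to
$10^{-12}$.

## Known limitations

* TRs are assumed constant within 5-year age groups and constant in time
  (scenario overrides excepted); the estimation aggregates five years of
  change into one annual matrix.
* Mortality does not differ by BMI category, so the model cannot express
  obesity-attributable excess mortality; migration is zero.
* The exponential-residence aging chain mixes cohorts within a group;
  it is not a single-year-of-age pipeline.
* Ages 60+ are outside the simulated system entirely.
* Under survey noise, $\tau_3$ and $\tau_4$ are weakly identified (see
  above); point estimates of them should not be over-read.
* The 2005 reconstruction is a stand-in, not the original inputs; results
  derived from it are illustrative.
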
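---
title: "A proportional multi-state life-table model of a sugar-sweetened beverage tax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A proportional multi-state life-table model of a sugar-sweetened beverage tax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbmslt)
```

## The question and the model

A volumetric excise on sugar-sweetened beverages (SSBs) changes consumer
prices; prices change demand; demand changes energy intake; energy intake
changes body-mass index (BMI); BMI changes the incidence of a long list of
chronic diseases; and disease incidence drives mortality, disability,
health-care spending — and, on the other side of the ledger, the tax raises
revenue. `ssbmslt` implements this whole causal chain as a cohort
simulation: a **proportional multi-state life table (MSLT)** in which every
modelled disease runs its own four-state Markov process (healthy, diseased,
dead from the disease, dead from other causes) and contributes its mortality
and disability *proportionally* to a shared life table, per one-year age and
sex cohort.

The population is a closed cohort of adults aged 20–100 in the base year
(2015), aged forward one year per cycle until everyone is dead or reaches
100. "Business as usual" is the comparator arm; each tax design is an
intervention arm. Health outcomes are disability-adjusted life years (DALYs,
read off the life table as health-adjusted person-years `Lw`) and
quality-adjusted life years (QALYs, built from BMI-category prevalences and
obesity-related utility weights); economic outcomes are health-care cost
offsets, tax revenue and intervention (administration) costs. The
cost-effectiveness comparison uses the public health-care payer perspective:
the ICER divides incremental health-care costs by incremental QALYs, and tax
revenue is a transfer that stays out of the ratio.

All inputs are synthetic. The package fabricates internally consistent,
Canada-like tables with known ground truth so that every stage is testable
without any survey, burden-of-disease or costing micro-data. Synthetic
values are placeholders with realistic magnitudes and shapes, not estimates
of the real Canadian quantities, so the interesting outputs of a run are
structural (directions, ratios, elasticity of the results to assumptions),
not the absolute totals.

## Stage by stage

### Price and demand

A flat tax of $\tau$ CAD/oz with pass-through $\phi$ on a baseline price
$p_0$ raises the price by $100\,\tau\phi/p_0$ percent. Defaults: $\tau$ =
0.015, $\phi$ = 1, $p_0$ = 0.10, hence +15%; the tax ladder also runs 0.01
and 0.02 (+10% / +20%), and sensitivity runs use $\phi$ = 0.8 and 1.2.

Demand responds linearly through an own/cross-price elasticity matrix $E$:
percent demand change = $E \times$ percent price change. The SSB own-price
elasticity is −1.15 (alternative matrix: −1.04 with fewer substitution
categories, used by the `alt_elasticities` sensitivity scenario), so the
base case yields a 17.25% consumption fall. Elasticities are identical
across age-sex strata; absolute differences come from baseline consumption
alone. Elasticity application is linear in percentage terms, not log-log
compounding — consistent with reading "15% price rise, 17% demand fall" as
$-1.15 \times 15$. Post-tax consumption is floored at zero.

The energy translation is this module's own construction: the SSB demand
change applies to each stratum's baseline SSB energy, and each substitute
category's demand change applies to that category's share of the stratum's
non-SSB energy. Cross-price terms toward SSB substitutes are small and
nonnegative in the generator, so substitution only dampens the energy drop:
$|\Delta TEI| \le |\Delta SSB|$ always holds, with roughly 5–10% of the SSB
energy cut given back.

### BMI

A sustained intake change of $\rho$ kcal/day moves steady-state body weight
by 1 kg; with height $h$, $\Delta BMI = (\Delta TEI/\rho)/h^2$. Default
$\rho$ = 22.5 kcal/day per kg (≈94 kJ), configurable and sampled in the
probabilistic analysis. The full steady-state effect is applied from the
first cycle and held for life — mirroring the one-time sustained consumption
change — and each cohort keeps the shift computed at its entry-age stratum.

Stratum BMI is a two-parameter continuous distribution, lognormal by
default (moment-matched to the stratum mean and SD; a normal family is a
config switch). The intervention shifts the mean only; the SD is untouched
(the model is silent on higher moments). A linear-in-calendar-year secular
trend (default ≈ +0.02 kg/m²/yr) shifts both arms identically, so it cancels
exactly in the arm difference of means but not in the nonlinear quantities
(category prevalences, PIFs); a `bmi_trend = FALSE` switch freezes means at
base-year values. Overweight is 25 < BMI ≤ 30 and obesity BMI > 30, with
the boundary assigned by exactly that convention; first-year
overweight+obesity cases prevented are the prevalence drop times the
stratum population, floored at zero per stratum.

### Potential impact fractions

The proportional change in disease risk from shifting the exposure
distribution $P$ to $P^*$ is

$$PIF = \frac{\int_l^h RR(x)P(x)\,dx - \int_l^h RR(x)P^*(x)\,dx}
             {\int_l^h RR(x)P(x)\,dx}$$

with a log-linear relative-risk curve $RR(x) = rr^{(x - TMREL)_+/5}$ per
5 kg/m² above a TMREL of 22.5 kg/m² (configurable). Two diseases (type 2
diabetes and ischaemic heart disease) additionally carry a direct
consumption pathway with an RR per serving/day on the SSB-intake
distribution; the two pathways multiply,
$i^* = i\,(1-PIF_{BMI})(1-PIF_{direct})$, a documented choice (the
alternative readings — additive or mediation-adjusted — are not
implemented), and the direct pathway can be switched off.

`compute_pif()` integrates by adaptive quadrature with bounds defaulting to
the 0.1th–99.9th percentiles of the comparator distribution. The production
pipeline uses an algebraically identical vectorised composite-Simpson path
(`.pif_grid`) on a shared exposure grid with a node placed exactly at the
TMREL kink; tests pin it to the adaptive path at 1e-6 and the adaptive path
to a 1e5-point Riemann oracle at 1e-6.

### Disease processes

Each disease evolves with constant within-cycle hazards: incidence,
remission (zero for the chronic-irreversible diseases the generator emits),
case fatality, and other-cause mortality. The annual cycle is the exact
matrix exponential of the intensity matrix: the live 2×2 block is
diagonalised in closed form (both eigenvalues real; a confluent branch
handles repeated eigenvalues), deaths accumulate as hazard-weighted
integrals of the live occupancies, and mass is conserved to machine
precision — competing risks cannot leak, unlike discrete annual
probabilities. Because other-cause mortality scales both live states
equally, prevalence among the living is computed with that hazard divided
out, which is exact and lets one recursion serve all cohorts.

Cohorts are assumed disease-free at age 20; prevalence at older entry ages
is accumulated by running the baseline hazards from 20 to the entry age, so
initial conditions are identical in both arms. Diseases are independent (no
comorbidity interaction).

### The life table and the ledgers

Residual rates strip the modelled diseases out of the all-cause inputs:
$m^- = m_{all} - \sum_d f_d p_d$ and $w^- = pYLD - \sum_d p_d\,dw_d$,
computed in the comparator arm (the synthetic generator calibrates hazard
scales so these residuals are positive everywhere — the feasibility
condition `validate_inputs()` re-checks). Each arm then adds its own disease
terms back: $q = 1 - e^{-m}$ (constant hazard within the year; the
actuarial conversion $m/(1+m/2)$ is available for cross-checks),
$l_{x+1} = l_x(1-q_x)$, $L_x = (l_x + l_{x+1})/2$ with an exponential tail
$L = l/m$ at the terminal age rather than truncation, and
$Lw_x = L_x(1 - w_x)$. DALYs averted are the arm difference in $Lw$ — no
age weights and no discounting inside the DALY itself. QALYs per year are
$L$ times the utility mix over BMI categories, so the gain combines the
utility effect of the obesity shift with the survival difference. Cost
offsets are comparator-minus-intervention prevalent-case-years times each
disease's annual cost; revenue accrues on post-tax consumption of the
living (the dead consume nothing and cost nothing); intervention cost is a
fixed 2% of revenue each year. Everything is discounted at 1.5%/yr with the
first model year undiscounted (3%/yr in sensitivity). The combined ICER is
the ratio of discounted totals (ratio of means); per-iteration ICERs are
also available from the PSA draws, and the two estimators need not agree
exactly — both are exposed rather than silently picking one.

### Uncertainty

The probabilistic analysis re-samples, once per iteration and shared across
strata: BMI means (normal, truncated at physical bounds), relative risks
(lognormal, one shared log-scale shift applied to both pathways), the
energy-balance constant (normal, relative), baseline SSB intake (normal on
each stratum mean with its standard error, one shared z) and the SSB
own-price elasticity (normal). Sharing draws across strata preserves the
correlation structure of a systematic parameter error. The study condition
is 2000 iterations (the `run_psa()` default); point estimates are means
over iterations and 95% uncertainty intervals are empirical percentiles.
The "Monte Carlo with bootstrapping" phrase is implemented as parametric
sampling of the named inputs; no resampling of micro-data exists here to
bootstrap. Failed iterations are excluded and counted; more than 1% aborts.

Five univariate scenarios run in deterministic mode: static BMI, 80% and
120% pass-through, 3% discounting, alternative elasticities — exactly one
parameter family each.

## The synthetic generator

The generator emulates the *shape* of the real inputs: Gompertz all-cause
mortality (female/male multipliers), logistic-in-age pYLD, a survival-shaped
population profile totalling ≈26M adults scaled by 1/1000 so a full run
takes under a second, 10-year-band consumption with male > female SSB
intake declining with age, age-specific BMI means near 26–28 kg/m² with
SD ≈ 4–4.6, and 27 diseases with exponential-in-age incidence and case
fatality. Grouped rates are generated on 5-year bands and interpolated to
single ages by a shape-preserving monotone (Fritsch–Carlson) cubic through
band midpoints with a band-mean correction (band means of the output
reproduce the band inputs within 2%), linear tangent extension beyond the
outermost midpoints, floored at zero. This interpolation replaces the
grouped-data smoothing role of dedicated epidemiological software; the
internal consistency-solving such software also performs (inferring one
hazard from the others) is *not* reproduced — instead hazards are generated
jointly and then calibrated deterministically so modelled-disease mortality
and disability never exceed 70% of the all-cause inputs in any cell.

What the generator does **not** emulate: survey weighting and measurement
error, cohort effects in consumption, disease-specific age shapes beyond
smooth exponentials, correlation between diseases, regional or
socio-economic heterogeneity, and any resemblance of the absolute hazard or
cost levels to the real Canadian values. Passing tests therefore certify
the *machinery* — the arithmetic chain, the quadrature, the Markov kernel,
the life-table accounting, the economic conventions and all the declared
invariants — on data whose ground truth is known; they say nothing about
the real-world magnitude of any tax effect.

## Numerical choices, sizes and edge cases

* PIF quadrature: adaptive `integrate` (rel.tol 1e-10) for the scalar path;
  composite Simpson with ≈241 nodes and a TMREL-kink split for the
  vectorised path. Bounds default to the 0.1th/99.9th percentiles.
* Identical comparator and intervention parameters short-circuit to *exact*
  zeros (PIF, and hence every downstream delta): a null tax or null
  elasticity reproduces the comparator bit-for-bit, which the tests assert
  as exact equality, not tolerance.
* The Markov kernel switches to the confluent (repeated-eigenvalue) branch
  when the discriminant is below 1e-10 relative; `expm1` guards the
  $(\!e^{\lambda t}-1)/\lambda$ integrals near $\lambda = 0$.
* The post-tax SSB-intake distribution floors its mean at 1% of the
  comparator mean so the lognormal family stays defined under extreme
  simulated taxes.
* Problem sizes: 81 ages × 2 sexes × 27 diseases is the default full run
  (~0.7 s); the test suite uses 2–4-disease bundles and the PSA
  self-consistency check runs 500 iterations; the analysis driver runs 400
  iterations and prints the Monte-Carlo SE so readers can judge the
  residual simulation error. The million-agent microsimulation oracle runs
  as 20 batches of 50,000 agents with batch-based standard errors.
* Seeds: every stochastic element (generation, PSA, test oracles) is
  seeded; regeneration under a fixed seed is byte-identical, verified by
  MD5 checksums over the written CSVs.

## Known limitations

One-time sustained demand change (no long-run demand dynamics or
reformulation); mean-shift-only BMI response; independence of diseases;
linear secular BMI trend; a single national pass-through rate; no
children/adolescents (their chronic-disease burden is negligible, but their
consumption response is not modelled into later-life risk); payer
perspective only (no productivity or informal-care costs); synthetic
placeholder magnitudes throughout.
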
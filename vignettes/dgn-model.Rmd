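---
title: "A dynamic gene network model of the maize floral transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic gene network model of the maize floral transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnmaize)
```

## The model

The shoot apical meristem of maize switches from making leaves to making
the tassel at the floral transition. The MADS-box gene *ZMM4* is a marker
of that switch: its mRNA rises roughly exponentially in the shoot apex and
peaks at the transition, consistently across genotypes. `dgnmaize`
implements a deliberately minimal dynamic gene network (DGN) built on that
observation. Three upstream genetic elements — *ID1*, *DLF1* and the QTL
*VGT1* — enter as fixed binary allele states (functional/early allele = 1),
and scaled ZMM4 abundance $m(t)$ is the single state variable:

$$\frac{dm}{dt} = \alpha_1\left(ID1 + \alpha_2\, ID1\cdot DLF1 +
\alpha_3\, VGT1 + \beta_{\mathrm{eff}}\right) + \omega\, m, \qquad m(0)=0.$$

The terms condense the simplified regulatory topology shipped as
`dgn_grn_edges()`:

* *ID1* acts both alone (autonomous path; its coefficient is fixed at 1 to
  anchor the scale) and through the florigen-carrier path, where the ZCN8
  protein complexes with DLF1 — hence an $ID1 \cdot DLF1$ interaction term
  weighted by $\alpha_2$ rather than an explicit ZCN8 node.
* *VGT1* represses the repressor *ZmRAP2.7*; the double repression
  collapses to a single positive term weighted by $\alpha_3$.
* $\beta$ is basal ZMM4 synthesis. A line carrying the constitutive
  ZMM4-overexpression transgene has two expressed copies, modelled
  conservatively as $\beta_{\mathrm{eff}} = 2\beta$
  (`zmm4_transgene = 1`).
* $\omega > 0$ is a positive ZMM4 feedback loop — the parsimonious way to
  produce the observed exponential rise.

Because every allele state is constant in time, the bracketed term is a
genotype-specific constant $c$ (`regulatory_input()`), and the equation is
linear with exact solution $m(t) = (c/\omega)(e^{\omega t}-1)$
(`dgn_closed_form()`). The floral transition status (FTS) switches to 1
when $m$ reaches a threshold $\theta$; the predicted days to tassel
initiation (DTI) is the crossing time, analytically
$t^* = \log(1+\omega\theta/c)/\omega$ (`dgn_analytic_dti()`).

A note on provenance: the functional form above is a reconstruction. The
placement of $\beta$ inside the $\alpha_1$ parenthesis follows the
description of $\alpha_1$ as a scaling factor that acts on all gene
effects *including* basal synthesis; its self-consistency is checked by
the genotype ordering tests below. Users probing alternative forms should
treat the equation, not the code, as the assumption.

## Numerical scheme

`dgn_simulate()` integrates by forward Euler,
$m_{k+1} = m_k + \Delta t\,(c + \omega m_k)$, evaluated as a linear
recursive filter. Defaults (all exposed in `dgn_settings()`):

| setting | default | units | why |
|---|---|---|---|
| `dt` | 0.01 | d | the reference analysis' step; crossing-time error ≈ 0.04% |
| `t_max` | 100 | d | safely beyond the latest genotype (~46 d), only $10^4$ steps |
| `m0` | 0 | scaled | negligible plant size at planting |
| `threshold` | 1 | scaled | expression is scaled so its transition peak is 1 |

DTI is linearly interpolated between the two Euler grid points bracketing
the crossing rather than snapped to the grid, so the calibration objective
is smooth in the parameters — Nelder-Mead degrades badly on
piecewise-constant objectives. The closed form provides an independent
oracle: the test suite requires the Euler crossing to agree within 0.5%
and the error to halve when `dt` halves (first-order convergence).

Two contract limitations. First, the model describes accumulation *up to*
the transition only; the post-peak decline of ZMM4 mRNA in real apices is
not modelled, and trajectory values beyond the crossing are extrapolation.
Second, if a trajectory cannot reach the threshold within `t_max`, a
classed warning (`dgn_horizon_exhausted`) is raised and `dti` is `NA`; the
calibration objective instead substitutes `t_max` as a finite pessimistic
surrogate so the optimizer is steered back toward feasibility rather than
faced with an infinite or flat objective.

The latching rule is a design choice the source material leaves open: FTS
latches at the *configured threshold* (default, the scaled peak 1.0), not
at each genotype's own observed maximum. Time zero is planting for every
genotype; the earliest sampled stages differ between genotypes in the
underlying study, but the model has no input that could use that
distinction.

## Calibration

`dgn_fit()` estimates $(\alpha_1, \alpha_2, \alpha_3, \beta, \omega)$ by
minimizing

$$SSE = \underbrace{\sum_g \sum_i (RNAp_{g,i} - RNAo_{g,i})^2}_{SSE_g}
      + \underbrace{\sum_g (DTIp_g - DTIo_g)^2}_{SSE_p}$$

where predicted expression is interpolated from the Euler grid at the
observed sampling times. The two components are summed with unit weights
even though their units differ (squared scaled expression vs squared
days); that matches the reference analysis, and `weight_phenotype` exposes
the balance for sensitivity checks. Raw expression must first be scaled by
the single global maximum across genotypes (`scale_expression()`), never
per genotype — a per-genotype scale would erase exactly the between-
genotype amplitude differences the model explains with allele states.

The optimizer is Nelder-Mead (`stats::optim`), run by default on
$\log$-parameters so every candidate stays strictly positive — the model
is meaningless for negative rates. Defaults (`dgn_control()`): relative
objective tolerance $10^{-10}$, 5000 iterations per run, 3 deterministic
restarts from the best point (restarting rebuilds a fresh simplex and is
the standard guard against premature collapse; no random jitter, so a fit
is reproducible from its starting vector alone). Tolerances down to
simplex size are not separately exposed because `optim`'s Nelder-Mead
controls convergence through the relative objective tolerance; the
restarts compensate.

Identifiability is checked before fitting: the forcing constants are
linear in the four regressors $(ID1,\ ID1\cdot DLF1,\ VGT1,\
\beta\text{-multiplier})$, so the observed panel must span four
independent allele combinations — the four training genotypes (Gaspe
Flint, B73, *dlf1*, *id1*) do exactly that, while e.g. \{B73, *id1*\}
spans two and is refused. `invert_closed_form()` complements this with an
exact algebraic inversion of the four training forcing constants, used in
the tests as a machine-precision oracle for the coefficient algebra.
$\omega$ is identified separately, by the curvature of the expression time
series.

For recovery experiments the default start (`dgn_perturb_start()`)
perturbs the generating truth by +50%/−33% alternating across
coordinates — far enough to exercise the optimizer, close enough to stay
in the basin. Real fits should supply their own starts (and ideally
several).

## The synthetic-data generator

No raw expression series or leaf-number tables accompany the study the
model comes from — both appear only as figures — so `dgn_synthesize()`
generates datasets with the *structure* the analysis assumes, and the
package's empirical claims are claims about that structure, not about the
unpublished measurements:

* sampling times: 10 per genotype, evenly spaced on $[0, t^*_g]$. The
  real cadence was genotype- and stage-dependent and is unrecoverable; an
  even grid up to the transition is the neutral stylization.
* expression: exact closed-form values plus additive Gaussian noise
  (default sd 0.02 on the 0–1 scale), clipped to $[0,1]$. No measurement
  error model is published; additive Gaussian with clipping is the
  simplest defensible choice.
* observed DTI: analytic $t^*_g$ plus Gaussian noise (default sd 0.5 d).
* total leaf number: $TLN_g = 12 + 0.35\, DTI_g + \varepsilon$ leaves
  (noise sd 1 leaf; negative draws resampled). The link is *fabricated
  calibration*, chosen once so B73 (DTI ≈ 21 d) carries ≈ 19–20 leaves, a
  realistic temperate value; it is not a measured relation.

Everything is bit-reproducible under a fixed seed. What passing tests on
these data do show: the estimator recovers generating coefficients (to
within 2% noiselessly; median error ≈ 1% per coordinate at expression
noise sd 0.02), the pipeline is deterministic, and the evaluation stage's
$R^2$ behaves as configured (`tln_noise_for_r2()` inverts
$R^2 = s^2_{fit}/(s^2_{fit}+\sigma^2)$). What they do not show: anything
about GeXP measurement noise, real sampling schedules, replicate
structure, or the field relation between leaf number and transition time —
in particular, the published $R^2 = 0.86$ against real leaf counts is not
reproducible from public information and is *not* a package claim.

## Evaluation

`dgn_predict_panel()` predicts DTI for arbitrary panels, including
genotypes never used in calibration — the *id1 dlf1* double mutant (whose
trajectory is provably identical to the *id1* single mutant: $ID1 = 0$
annihilates both ID1 terms) and the three transgenic lines (strictly
earlier than their backgrounds, since $c$ is increasing in
$\beta_{\mathrm{eff}}$). `tln_dti_regression()` then regresses observed
mean TLN on predicted DTI by OLS — TLN as the response, genotype means
rather than per-plant values, unweighted (replicate counts per genotype
are not available to weight by). `check_ordering()` verifies the
qualitative ranking Gaspe < B73 < *dlf1* ≤ *id1* with the double mutant
tied to *id1*.

One published-table wrinkle: the allele table lists the transgenic *id1*
line with $ID1 = 1, DLF1 = 0$ and the transgenic *dlf1* line with the
reverse — contradicting the genotype names (the untagged single-mutant
rows are name-consistent, suggesting a column swap in the two transgenic
rows). The default panel derives allele states from the names;
`dgn_example_panel("as_printed")` reproduces the printed rows for anyone
wanting the literal table.

## A worked run

```{r workflow, eval = FALSE}
truth <- dgn_published_params()
panel <- dgn_example_panel(training = TRUE)

synth <- dgn_synthesize(truth, panel, rna_noise_sd = 0, dti_noise_sd = 0)
fit <- dgn_fit(synth$observations, start = dgn_perturb_start(truth))
summary(fit)
plot(fit)

pred <- dgn_predict_panel(dgn_example_panel(), coef(fit))
check_ordering(pred)
```

Problem sizes used throughout the package's own tests: 4–8 genotypes,
10 samples per genotype, Euler step 0.01 d over a 100 d horizon, 6–50
seeded replicates per stochastic property. These are the scales at which
the model's claims are sharp; nothing in the method caps them.

## Known limitations

* The DGN has no environmental inputs — no photoperiod, temperature or
  circadian forcing — so it cannot transfer across environments; allele
  states are its only covariates.
* Only the four selected network nodes are modelled; the wider candidate-
  gene network is background, not dynamics.
* Point estimation only: no bootstrap or profile-likelihood uncertainty,
  matching the scope of the original analysis.
* The transgene rule $\beta_{\mathrm{eff}} = 2\beta$ is conservative;
  constitutive promoters likely overexpress by more, which would make
  transgenic DTI predictions systematically late.
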
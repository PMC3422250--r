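# dgnmaize

A dynamic gene network (DGN) model of the floral transition in maize, for
researchers studying flowering-time genetics and gene-to-phenotype
modelling. The shoot apical meristem's switch from leaf production to
tassel initiation is marked by the expression peak of the MADS-box gene
*ZMM4*; this package models scaled ZMM4 mRNA abundance $m(t)$ with a
logic-gated linear ODE driven by the binary allele states of *ID1*,
*DLF1* and *VGT1*:

$$\frac{dm}{dt} = \alpha_1\left(ID1 + \alpha_2\,ID1\cdot DLF1 +
\alpha_3\,VGT1 + \beta_{\mathrm{eff}}\right) + \omega\,m,\qquad m(0)=0,$$

with $\beta_{\mathrm{eff}} = 2\beta$ for lines carrying a constitutive
*ZMM4* overexpression transgene. The predicted days to tassel initiation
(DTI) is the time at which $m$ reaches a threshold (1.0 on the shared
expression scale). The package provides:

* forward-Euler simulation (`dgn_simulate()`, `predict_dti()`) with an
  exact closed-form oracle (`dgn_closed_form()`, `dgn_analytic_dti()`);
* calibration of the five coefficients
  $(\alpha_1,\alpha_2,\alpha_3,\beta,\omega)$ by Nelder-Mead on a combined
  expression + phenotype sum-of-squares objective (`dgn_fit()`, with the
  usual `coef`/`summary`/`predict`/`plot`/`residuals`/`simulate`
  methods);
* a seeded synthetic-data generator for parameter-recovery and evaluation
  studies (`dgn_synthesize()`) — the study's raw expression and leaf-number
  data were published only graphically, so all shipped data are synthetic
  or transcribed tables;
* evaluation: panel-wide DTI prediction (`dgn_predict_panel()`),
  regression of total leaf number on predicted DTI
  (`tln_dti_regression()`), and the qualitative genotype-ordering check
  (`check_ordering()`);
* a file-based pipeline front end (`dgn_run()`; thin CLI wrapper in
  `inst/scripts/dgn.R`).

See `vignettes/dgn-model.Rmd` for the model's assumptions, numerical
choices and limitations.

## Worked example

Recover the shipped reference coefficients from noiseless synthetic data
for the four training genotypes, then predict the full eight-genotype
panel:

```r
library(dgnmaize)
truth <- dgn_published_params()
panel <- dgn_example_panel(training = TRUE)

synth <- dgn_synthesize(truth, panel, rna_noise_sd = 0, dti_noise_sd = 0)
fit <- dgn_fit(synth$observations, start = dgn_perturb_start(truth))
summary(fit)
#> Coefficients:
#>    alpha1    alpha2    alpha3      beta     omega
#>  0.002001  6.489431 53.204800  0.821720  0.086820
#>
#> Objective: SSE = 9.02066e-14 = SSEg 8.64143e-14 (on 40 expression samples) + SSEp 3.79232e-15
#> Optimizer: converged, 2020 objective evaluations
```

Every coefficient comes back within 0.05% of the generating values
(alpha1 0.002, alpha2 6.489431, alpha3 53.204799, beta 0.821720, omega
0.086782); the residual SSE of 9e-14 is the Euler discretization floor.

```r
pred <- dgn_predict_panel(dgn_example_panel(), coef(fit))
pred
#>          name    dti reached
#> 1         B73 21.063    TRUE
#> 2         id1 45.924    TRUE
#> 3        dlf1 37.008    TRUE
#> 4  GaspeFlint  6.151    TRUE
#> 5    id1_dlf1 45.924    TRUE
#> 6  ZMM4oe_B73 20.158    TRUE
#> 7  ZMM4oe_id1 38.149    TRUE
#> 8 ZMM4oe_dlf1 32.925    TRUE
check_ordering(pred)
#> GaspeFlint<B73       B73<dlf1      dlf1<=id1  id1==id1_dlf1
#>           TRUE           TRUE           TRUE           TRUE
```

The early Gaspe Flint landrace transitions at ~6 d, B73 at ~21 d, the
late *dlf1* and *id1* mutants at ~37 and ~46 d; the *id1 dlf1* double
mutant is exactly as late as the *id1* single mutant (losing ID1 removes
both ID1-dependent terms), and every transgenic line is earlier than its
background. Regressing synthetic leaf counts on these predictions:

```r
s2 <- dgn_synthesize(truth, dgn_example_panel(),
                     tln_noise_sd = tln_noise_for_r2(pred$dti, 0.35, 0.86))
tln_dti_regression(pred, s2$tln)
#> TLN ~ predicted DTI (n = 8 genotypes)
#>   TLN = 13.773 + 0.3351 * DTI,  R^2 = 0.929
```

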
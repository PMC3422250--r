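test_that("expression scaling divides by the single global maximum", {
  expect_equal(scale_expression(c(2, 4, 8)), c(0.25, 0.5, 1.0))
  # shared denominator across genotypes
  df <- data.frame(name = c("a", "a", "b", "b"), time = c(1, 2, 1, 2),
                   value = c(1, 5, 2, 10))
  out <- scale_expression(df)
  expect_equal(out$rna, c(0.1, 0.5, 0.2, 1.0))
  # idempotent on already-scaled data
  expect_equal(scale_expression(out$rna), out$rna)
  expect_error(scale_expression(c(0, 0, 0)), "positive")
})

test_that("observation bundles are validated against the panel", {
  panel <- training_panel()
  ex <- data.frame(name = "B73", time = c(0, 5, 10), rna = c(0, 0.2, 0.5))
  dti <- data.frame(name = "B73", dti_obs = 21)
  obs <- dgn_observations(ex, dti, panel)
  expect_s3_class(obs, "dgn_observations")

  expect_error(
    dgn_observations(transform(ex, name = "Mo17"), dti, panel), "Mo17")
  expect_error(
    dgn_observations(ex[c(1, 3, 2), ], dti, panel), "increasing")
  expect_error(
    dgn_observations(ex[1:2, ][c(1, 1), ], dti, panel), "increasing")
  expect_error(
    dgn_observations(transform(ex, rna = rna * 3), dti, panel), "0, 1")
  expect_error(
    dgn_observations(ex[1, ], dti, panel), "at least two")
})

test_that("the objective decomposes exactly and vanishes on exact data", {
  p <- ref_params()
  panel <- training_panel()
  synth <- dgn_synthesize(p, panel, rna_noise_sd = 0, dti_noise_sd = 0,
                          seed = 1)
  parts <- dgn_objective(p, synth$observations)
  # noiseless closed-form data leave only the Euler discretization floor
  expect_lt(parts$sse, 1e-3)
  expect_identical(parts$sse, parts$sse_g + parts$sse_p)

  # perturbing any single coefficient away from the truth raises the SSE
  for (nm in names(p)) {
    for (f in c(0.9, 1.1)) {
      q <- unclass(p)
      q[nm] <- q[nm] * f
      expect_gt(dgn_objective(as_dgn_params(q), synth$observations)$sse,
                parts$sse)
    }
  }
})

test_that("an empty observation set has zero objective", {
  panel <- training_panel()
  obs <- dgn_observations(
    data.frame(name = character(), time = numeric(), rna = numeric()),
    data.frame(name = character(), dti_obs = numeric()), panel)
  parts <- dgn_objective(ref_params(), obs)
  expect_identical(parts, list(sse_g = 0, sse_p = 0, sse = 0))
})

test_that("the phenotype weight rebalances the objective components", {
  p <- ref_params()
  synth <- dgn_synthesize(p, training_panel(), rna_noise_sd = 0.05,
                          dti_noise_sd = 1, seed = 3)
  q <- dgn_perturb_start(p)
  w0 <- dgn_objective(q, synth$observations, weight_phenotype = 0)
  w2 <- dgn_objective(q, synth$observations, weight_phenotype = 2)
  expect_equal(w0$sse, w0$sse_g)
  expect_equal(w2$sse, w2$sse_g + 2 * w2$sse_p)
})

test_that("algebraic inversion of the training forcing constants is exact", {
  p <- ref_params()
  cs <- regulatory_input(training_panel(), p)
  rec <- invert_closed_form(cs[["id1"]], cs[["dlf1"]], cs[["B73"]],
                            cs[["GaspeFlint"]], p[["omega"]])
  expect_equal(unclass(rec), unclass(p), tolerance = 1e-12)

  expect_error(invert_closed_form(0.2, 0.2, 0.3, 0.4, 0.1), "degenerate")
  # equal spacing anywhere in the chain is uninformative and refused
  expect_error(invert_closed_form(1, 2, 2, 2, 0.1), "degenerate")
})

test_that("a rank-deficient allele design is refused before fitting", {
  p <- ref_params()
  panel <- dgn_panel(dgn_genotype("B73", 0, 1, 1),
                     dgn_genotype("id1", 0, 0, 1))
  ex <- do.call(rbind, lapply(panel$name, function(g) {
    c_g <- unname(regulatory_input(panel[panel$name == g, ], p))
    tt <- seq(1, 20, length.out = 5)
    data.frame(name = g, time = tt,
               rna = pmin(1, m_exact(c_g, p[["omega"]], tt)))
  }))
  dti <- data.frame(name = panel$name, dti_obs = c(21, 46))
  obs <- dgn_observations(ex, dti, panel)
  expect_error(dgn_fit(obs, start = p), "degenerate design")
})

test_that("starting at the truth on noiseless data is a fixed point", {
  p <- ref_params()
  synth <- dgn_synthesize(p, training_panel(), rna_noise_sd = 0,
                          dti_noise_sd = 0, seed = 1)
  fit <- dgn_fit(synth$observations, start = p,
                 control = dgn_control(maxit = 2000, restarts = 0))
  expect_true(fit$convergence)
  expect_lt(fit$sse, 1e-3)
  expect_equal(coef(fit), unclass(p), tolerance = 0.005)
  expect_identical(fit$sse, fit$sse_g + fit$sse_p)
})

test_that("log-space optimization keeps every candidate coefficient positive", {
  p <- ref_params()
  synth <- dgn_synthesize(p, training_panel(), rna_noise_sd = 0.1,
                          dti_noise_sd = 2, seed = 5)
  fit <- suppressWarnings(
    dgn_fit(synth$observations, start = dgn_perturb_start(p),
            control = dgn_control(maxit = 300, restarts = 0)))
  expect_true(all(coef(fit) > 0))
})

test_that("fit methods expose coefficients, predictions and residuals", {
  p <- ref_params()
  synth <- dgn_synthesize(p, training_panel(), rna_noise_sd = 0.02,
                          dti_noise_sd = 0.5, seed = 2)
  fit <- suppressWarnings(
    dgn_fit(synth$observations, start = p,
            control = dgn_control(maxit = 400, restarts = 0)))
  expect_named(coef(fit), c("alpha1", "alpha2", "alpha3", "beta", "omega"))
  pred <- predict(fit)
  expect_setequal(pred$name, training_panel()$name)
  f <- fitted(fit)
  expect_equal(nrow(f), nrow(synth$observations$expression))
  r <- residuals(fit)
  expect_equal(r$residual, synth$observations$expression$rna - f$fitted)
  rd <- residuals(fit, type = "dti")
  expect_equal(nrow(rd), 4)
  s <- summary(fit)
  expect_s3_class(s, "summary.dgn_fit")
  expect_output(print(s), "SSEg")
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]]$observations, "dgn_observations")
})

test_that("recovery stays within 10% per coordinate under expression noise", {
  p <- ref_params()
  panel <- training_panel()
  errs <- sapply(1:6, function(s) {
    synth <- dgn_synthesize(p, panel, rna_noise_sd = 0.02,
                            dti_noise_sd = 0, seed = s)
    fit <- suppressWarnings(
      dgn_fit(synth$observations, start = dgn_perturb_start(p),
              control = dgn_control(maxit = 1500, restarts = 0,
                                    reltol = 1e-9)))
    abs(coef(fit) - unclass(p)) / unclass(p)
  })
  expect_true(all(apply(errs, 1, stats::median) < 0.10))
})
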
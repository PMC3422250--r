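test_that("regulatory input combines allele states and coefficients correctly", {
  p <- ref_params()
  gaspe <- dgn_genotype("GaspeFlint", vgt1 = 1, id1 = 1, dlf1 = 1)
  # 0.002 * (1 + 6.489431 + 53.204799 + 0.821720)
  expect_equal(unname(regulatory_input(gaspe, p)), 0.12303190)

  id1_mut <- dgn_genotype("id1", vgt1 = 0, id1 = 0, dlf1 = 1)
  dbl_mut <- dgn_genotype("id1_dlf1", vgt1 = 0, id1 = 0, dlf1 = 0)
  expect_equal(unname(regulatory_input(id1_mut, p)), 0.00164344)
  # ID1 = 0 annihilates both the ID1 and ID1*DLF1 terms: the id1 single
  # mutant and the double mutant have identical forcing
  expect_identical(unname(regulatory_input(id1_mut, p)),
                   unname(regulatory_input(dbl_mut, p)))

  # transgene doubles the basal-synthesis contribution
  tg <- dgn_genotype("tg", vgt1 = 0, id1 = 1, dlf1 = 1, zmm4_transgene = 1)
  b73 <- dgn_genotype("B73", vgt1 = 0, id1 = 1, dlf1 = 1)
  expect_equal(unname(regulatory_input(tg, p) - regulatory_input(b73, p)),
               p[["alpha1"]] * p[["beta"]])

  # vectorized over a panel, named by genotype
  cs <- regulatory_input(full_panel(), p)
  expect_named(cs, full_panel()$name)
  expect_true(all(cs > 0))
})

test_that("genotype and parameter validation rejects out-of-range values", {
  expect_error(dgn_genotype("x", vgt1 = 2, id1 = 1, dlf1 = 1), "0 or 1")
  expect_error(dgn_panel(dgn_genotype("a", 0, 1, 1),
                         dgn_genotype("a", 1, 1, 1)), "unique")
  expect_error(dgn_params(0.002, -1, 53, 0.8, 0.09), "positive")
  expect_error(dgn_params(0, 6.5, 53, 0.8, 0.09), "positive")
})

test_that("the derivative is forcing plus linear feedback", {
  p <- ref_params()
  expect_equal(dgn_derivative(0, 0.5, p), 0.5)
  expect_equal(dgn_derivative(1, 0.0166223, p),
               0.0166223 + 0.086782)
  p0 <- dgn_params(0.002, 6.489431, 53.204799, 0.821720, omega = 1e-300)
  expect_equal(dgn_derivative(10, 0.3, p0), 0.3)
})

test_that("the closed form solves the linear equation and its omega -> 0 limit", {
  expect_equal(dgn_closed_form(0.5, 0.1, 0), 0)
  expect_equal(dgn_closed_form(0.5, 0, 3), 1.5)
  # continuity at omega = 0
  expect_equal(dgn_closed_form(0.5, 1e-12, 3), 1.5, tolerance = 1e-9)
  # B73 forcing reaches the threshold at its analytic crossing time
  expect_equal(dgn_closed_form(0.0166223, 0.086782, 21.063), 1.0,
               tolerance = 1e-3)
})

test_that("Euler trajectories agree with the exact solution to first order", {
  p <- ref_params()
  panel <- full_panel()
  for (i in seq_len(nrow(panel))) {
    g <- panel[i, , drop = FALSE]
    c_g <- unname(regulatory_input(g, p))
    exact_dti <- t_star(c_g, p[["omega"]])
    tr <- dgn_simulate(g, p)
    # relative deviation from the exact trajectory over [0, dti]
    keep <- tr$times <= exact_dti & tr$mzmm4 > 1e-6
    exact <- m_exact(c_g, p[["omega"]], tr$times[keep])
    expect_lt(max(abs(tr$mzmm4[keep] - exact) / exact), 0.005)
    expect_equal(tr$dti, exact_dti, tolerance = 0.005)
  }
})

test_that("halving the step roughly halves the integration error", {
  p <- ref_params()
  b73 <- dgn_genotype("B73", vgt1 = 0, id1 = 1, dlf1 = 1)
  exact_dti <- t_star(unname(regulatory_input(b73, p)), p[["omega"]])
  err <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    abs(predict_dti(b73, p, dgn_settings(dt = dt)) - exact_dti)
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.6)
  expect_lt(err[1] / err[2], 2.4)
  expect_gt(err[2] / err[3], 1.6)
  expect_lt(err[2] / err[3], 2.4)
})

test_that("trajectory invariants hold: monotone rise, latched FTS, DTI stability", {
  p <- ref_params()
  b73 <- dgn_genotype("B73", vgt1 = 0, id1 = 1, dlf1 = 1)
  tr <- dgn_simulate(b73, p)
  expect_equal(tr$times[1], 0)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(diff(tr$mzmm4) > 0))
  expect_true(all(tr$fts %in% c(0L, 1L)))
  expect_true(all(diff(tr$fts) >= 0))
  # FTS is 0 strictly before the crossing and 1 from the bracketing point on
  expect_true(all(tr$fts[tr$times < tr$dti - 0.01] == 0L))
  expect_true(all(tr$fts[tr$times >= tr$dti] == 1L))
  # DTI does not depend on the horizon once the horizon exceeds it
  expect_equal(predict_dti(b73, p, dgn_settings(t_max = 30)),
               predict_dti(b73, p, dgn_settings(t_max = 200)))
})

test_that("transition time is monotone in every regulatory contribution", {
  p <- ref_params()
  base <- dgn_genotype("base", vgt1 = 0, id1 = 0, dlf1 = 0)
  dti_base <- predict_dti(base, p)
  # adding VGT1, setting ID1, or doubling beta never delays the transition
  expect_lt(predict_dti(dgn_genotype("v", 1, 0, 0), p), dti_base)
  expect_lt(predict_dti(dgn_genotype("i", 0, 1, 0), p), dti_base)
  expect_lt(predict_dti(dgn_genotype("t", 0, 0, 0, 1), p), dti_base)
  # and across nested allele stacks the ordering is strict
  stack <- c(predict_dti(dgn_genotype("i", 0, 1, 0), p),
             predict_dti(dgn_genotype("id", 0, 1, 1), p),
             predict_dti(dgn_genotype("idv", 1, 1, 1), p))
  expect_true(all(diff(stack) < 0))
})

test_that("an unreachable threshold is signalled, not silently dropped", {
  p <- ref_params()
  dbl <- dgn_genotype("id1_dlf1", vgt1 = 0, id1 = 0, dlf1 = 0)
  expect_warning(tr <- dgn_simulate(dbl, p, dgn_settings(t_max = 10)),
                 class = "dgn_horizon_exhausted")
  expect_false(tr$reached)
  expect_true(is.na(tr$dti))
  expect_true(all(tr$fts == 0L))
})

test_that("a zero-input genotype needs positive basal synthesis to move", {
  # with all alleles 0 the forcing reduces to alpha1 * beta_eff > 0,
  # so the trajectory still rises, just slowly
  p <- ref_params()
  dbl <- dgn_genotype("null", vgt1 = 0, id1 = 0, dlf1 = 0)
  expect_equal(unname(regulatory_input(dbl, p)),
               p[["alpha1"]] * p[["beta"]])
})
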
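# Shared fixtures. ref_params() is the published coefficient vector the
# recovery experiments use as generating truth; t_star() is an in-test
# analytic crossing-time oracle, written out independently of the
# package's dgn_analytic_dti().

ref_params <- function() {
  dgn_params(alpha1 = 0.002000, alpha2 = 6.489431, alpha3 = 53.204799,
             beta = 0.821720, omega = 0.086782)
}

training_panel <- function() dgn_example_panel(training = TRUE)

full_panel <- function() dgn_example_panel()

# exact crossing time of dm/dt = c + w m, m(0) = 0, at threshold th
t_star <- function(c, w, th = 1) {
  if (w == 0) th / c else log(1 + w * th / c) / w
}

# exact solution at time t (independent restatement of the closed form)
m_exact <- function(c, w, t) {
  if (w == 0) c * t else (c / w) * (exp(w * t) - 1)
}
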
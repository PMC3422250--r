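#' Simulation settings
#'
#' Numerical settings for the forward-Euler integration of the ZMM4
#' equation. Time is in days after planting; expression is on the shared
#' 0–1 scale.
#'
#' @param dt Integration step (days). The reference analysis used 0.01 d.
#' @param t_max Simulation horizon (days). Default 100 d — safely beyond
#'   the latest genotype's transition (about 46 d) at modest cost
#'   (10^4 Euler steps).
#' @param m0 Initial scaled ZMM4 level; 0 reflects the negligible plant
#'   size at planting.
#' @param threshold Scaled ZMM4 level that marks the floral transition
#'   (FTS switches from 0 to 1). Expression is scaled so its peak, which
#'   coincides with the transition, is 1; hence the default 1.0.
#' @return A list of class \code{"dgn_settings"}.
#' @export
dgn_settings <- function(dt = 0.01, t_max = 100, m0 = 0, threshold = 1) {
  stopifnot(dt > 0, t_max > 0, m0 >= 0, threshold > m0)
  structure(list(dt = dt, t_max = t_max, m0 = m0, threshold = threshold),
            class = "dgn_settings")
}

#' Genotype-specific regulatory input (forcing rate)
#'
#' The constant, time-independent additive term of the ZMM4 equation for a
#' given genotype:
#' \deqn{c = \alpha_1 (ID1 + \alpha_2\, ID1\cdot DLF1 + \alpha_3\, VGT1 +
#'   \beta_{eff})}
#' with \eqn{\beta_{eff} = 2\beta} when the genotype carries the ZMM4
#' overexpression transgene (two expressed gene copies), else \eqn{\beta}.
#' The ID1 main-effect coefficient is fixed at 1; \code{alpha2} acts only
#' through the ID1-by-DLF1 product, so ID1 = 0 annihilates both ID1 terms.
#'
#' @param genotype A \code{"dgn_genotype"} (or one-row panel); a multi-row
#'   panel returns one rate per row, named by genotype.
#' @param params A \code{"dgn_params"} vector.
#' @return Forcing rate(s), per day; strictly positive for valid inputs.
#' @examples
#' gaspe <- dgn_genotype("GaspeFlint", vgt1 = 1, id1 = 1, dlf1 = 1)
#' regulatory_input(gaspe, dgn_published_params())
#' @export
regulatory_input <- function(genotype, params) {
  panel <- as_dgn_panel(genotype)
  params <- as_dgn_params(params)
  beta_eff <- params[["beta"]] * ifelse(panel$zmm4_transgene == 1, 2, 1)
  c_g <- params[["alpha1"]] *
    (panel$id1 + params[["alpha2"]] * panel$id1 * panel$dlf1 +
       params[["alpha3"]] * panel$vgt1 + beta_eff)
  names(c_g) <- panel$name
  c_g
}

#' Instantaneous rate of change of scaled ZMM4 expression
#'
#' \code{dm/dt = c + omega * m}: the genotype's constant regulatory input
#' plus the positive-feedback term. The feedback is the model's reading of
#' the exponential rise of ZMM4 mRNA toward its peak at the floral
#' transition.
#'
#' @param m Scaled ZMM4 level(s), non-negative.
#' @param c Forcing rate (per day), from [regulatory_input()].
#' @param params A \code{"dgn_params"} vector (only \code{omega} is used).
#' @return Rate(s) of change, per day.
#' @export
dgn_derivative <- function(m, c, params) {
  params <- as_dgn_params(params)
  c + params[["omega"]] * m
}

#' Analytic solution of the expression equation
#'
#' Exact solution of \code{dm/dt = c + omega * m} with \code{m(0) = 0}:
#' \deqn{m(t) = (c/\omega)(e^{\omega t} - 1)} for \eqn{\omega \neq 0} and
#' \eqn{m(t) = c\,t} for \eqn{\omega = 0} (the continuous limit, evaluated
#' via \code{expm1} so small \eqn{\omega} is handled stably). Serves as the
#' independent oracle for the Euler integrator and as the noiseless data
#' generator.
#'
#' @param c Forcing rate (per day).
#' @param omega Feedback rate (per day), may be 0.
#' @param t Time(s) in days, non-negative.
#' @return Scaled expression level(s) at \code{t}.
#' @export
dgn_closed_form <- function(c, omega, t) {
  stopifnot(all(t >= 0))
  if (omega == 0) c * t else (c / omega) * expm1(omega * t)
}

#' Analytic threshold-crossing time
#'
#' Inverts [dgn_closed_form()] at the transition threshold:
#' \deqn{t^* = \log(1 + \omega\,\theta/c)/\omega} (or \eqn{\theta/c} when
#' \eqn{\omega = 0}). This is the exact days-to-tassel-initiation implied
#' by the continuous model.
#'
#' @param c Forcing rate (per day), strictly positive.
#' @param omega Feedback rate (per day).
#' @param threshold Scaled expression level defining the transition.
#' @return Crossing time in days.
#' @export
dgn_analytic_dti <- function(c, omega, threshold = 1) {
  stopifnot(all(c > 0), threshold > 0)
  if (omega == 0) threshold / c else log1p(omega * threshold / c) / omega
}

#' Simulate a ZMM4 expression trajectory by forward Euler
#'
#' Integrates \code{dm/dt = c + omega * m} from \code{m0} at t = 0 with the
#' explicit Euler update \eqn{m_{k+1} = m_k + dt\,(c + \omega m_k)},
#' evaluated as a linear recurrence. The floral-transition status (FTS)
#' latches to 1 from the first grid point at or above the threshold; the
#' days to tassel initiation (DTI) is the crossing time, linearly
#' interpolated between the bracketing grid points so downstream objectives
#' are smooth in the parameters.
#'
#' The model describes accumulation up to the transition only; the
#' post-peak decline of ZMM4 expression seen in shoot apices is outside its
#' contract, and trajectory values beyond the crossing are extrapolation.
#'
#' If the threshold is not reached by \code{t_max} a
#' \code{"dgn_horizon_exhausted"} warning is signalled and \code{dti} is
#' \code{NA}.
#'
#' @param genotype A \code{"dgn_genotype"} (one row).
#' @param params A \code{"dgn_params"} vector.
#' @param settings A \code{"dgn_settings"} list.
#' @return An object of class \code{"dgn_trajectory"}: a list with
#'   \code{times}, \code{mzmm4}, \code{fts} (0/1 per grid point),
#'   \code{dti} (days, or \code{NA}), \code{reached} (logical),
#'   \code{genotype}, \code{forcing}.
#' @examples
#' b73 <- dgn_genotype("B73", vgt1 = 0, id1 = 1, dlf1 = 1)
#' tr <- dgn_simulate(b73, dgn_published_params())
#' tr$dti
#' @export
dgn_simulate <- function(genotype, params, settings = dgn_settings()) {
  panel <- as_dgn_panel(genotype)
  if (nrow(panel) != 1L)
    stop("dgn_simulate() takes a single genotype; see dgn_predict_panel()",
         call. = FALSE)
  params <- as_dgn_params(params)
  c_g <- unname(regulatory_input(panel, params))
  omega <- params[["omega"]]
  n <- ceiling(settings$t_max / settings$dt)
  times <- seq(0, by = settings$dt, length.out = n + 1L)
  # m_{k+1} = m_k (1 + omega dt) + c dt, a first-order recursive filter
  incr <- rep.int(c_g * settings$dt, n)
  m <- c(settings$m0,
         as.numeric(stats::filter(incr, 1 + omega * settings$dt,
                                  method = "recursive",
                                  init = settings$m0)))
  cross <- match(TRUE, m >= settings$threshold)
  if (is.na(cross)) {
    reached <- FALSE
    dti <- NA_real_
    warning(warningCondition(
      sprintf("genotype '%s': threshold %.3g not reached within t_max = %g d",
              panel$name, settings$threshold, settings$t_max),
      class = "dgn_horizon_exhausted"))
  } else {
    reached <- TRUE
    dti <- if (cross == 1L) times[1L] else {
      k <- cross
      times[k - 1L] + settings$dt *
        (settings$threshold - m[k - 1L]) / (m[k] - m[k - 1L])
    }
  }
  fts <- as.integer(cummax(m >= settings$threshold))
  structure(list(times = times, mzmm4 = m, fts = fts, dti = dti,
                 reached = reached, genotype = panel, forcing = c_g,
                 settings = settings),
            class = "dgn_trajectory")
}

#' Predict days to tassel initiation for one genotype
#'
#' Convenience wrapper around [dgn_simulate()] returning only the
#' threshold-crossing time. Agrees with the analytic crossing time
#' [dgn_analytic_dti()] up to first-order Euler error.
#'
#' @inheritParams dgn_simulate
#' @return Predicted DTI in days (\code{NA}, with a
#'   \code{"dgn_horizon_exhausted"} warning, if the horizon is exhausted).
#' @export
predict_dti <- function(genotype, params, settings = dgn_settings()) {
  dgn_simulate(genotype, params, settings)$dti
}

#' @export
print.dgn_trajectory <- function(x, ...) {
  cat(sprintf("ZMM4 trajectory for '%s' (forcing %.6g /d)\n",
              x$genotype$name, x$forcing))
  cat(sprintf("  grid: %d points, dt = %g d, horizon %g d\n",
              length(x$times), x$settings$dt, x$settings$t_max))
  if (x$reached)
    cat(sprintf("  floral transition at DTI = %.2f d (threshold %.3g)\n",
                x$dti, x$settings$threshold))
  else
    cat("  threshold not reached within the horizon\n")
  invisible(x)
}

#' @export
plot.dgn_trajectory <- function(x, ..., to_crossing = TRUE) {
  keep <- if (to_crossing && x$reached) x$times <= x$dti * 1.02 else TRUE
  graphics::plot(x$times[keep], x$mzmm4[keep], type = "l",
                 xlab = "days after planting", ylab = "scaled ZMM4 mRNA",
                 main = x$genotype$name, ...)
  graphics::abline(h = x$settings$threshold, lty = 3)
  if (x$reached) graphics::abline(v = x$dti, lty = 3)
  invisible(x)
}
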
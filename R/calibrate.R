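#' Scale raw expression measurements to the shared 0-1 range
#'
#' Divides every raw value by the single global maximum across all
#' genotypes and sampling times (one shared denominator, not per-genotype),
#' so the largest observation becomes exactly 1.0 and relative differences
#' between genotypes are preserved. Only samples taken at or before each
#' genotype's floral transition should be included, since the model
#' describes the pre-transition rise only.
#'
#' @param x Either a numeric vector of raw values, or a long-format data
#'   frame with columns \code{name}, \code{time}, \code{value}.
#' @return Scaled values in the same shape as the input (for a data frame,
#'   the \code{value} column is replaced by \code{rna}).
#' @examples
#' scale_expression(c(2, 4, 8))
#' @export
scale_expression <- function(x) {
  if (is.numeric(x)) {
    mx <- max(x, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0)
      stop("expression scaling needs at least one strictly positive value",
           call. = FALSE)
    return(x / mx)
  }
  stopifnot(is.data.frame(x), all(c("name", "time", "value") %in% names(x)))
  out <- x
  out$rna <- scale_expression(x$value)
  out$value <- NULL
  out
}

#' Bundle calibration observations
#'
#' Packages, per genotype, a scaled ZMM4 expression time series and an
#' observed days-to-tassel-initiation value, validated against a genotype
#' panel: every observed genotype must be in the panel, sampling times must
#' be strictly increasing with at least two points per genotype, and scaled
#' expression must lie in [0, 1].
#'
#' @param expression Long-format data frame with columns \code{name},
#'   \code{time} (days), \code{rna} (scaled expression).
#' @param dti Data frame with columns \code{name}, \code{dti_obs} (days).
#' @param panel A \code{"dgn_panel"} covering all observed genotypes.
#' @return An object of class \code{"dgn_observations"}.
#' @export
dgn_observations <- function(expression, dti, panel) {
  panel <- as_dgn_panel(panel)
  stopifnot(is.data.frame(expression),
            all(c("name", "time", "rna") %in% names(expression)),
            is.data.frame(dti), all(c("name", "dti_obs") %in% names(dti)))
  expression <- expression[c("name", "time", "rna")]
  dti <- dti[c("name", "dti_obs")]
  obs_names <- union(unique(expression$name), dti$name)
  unknown <- setdiff(obs_names, panel$name)
  if (length(unknown))
    stop("observed genotype(s) not in the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(dti$name))
    stop("one observed DTI per genotype, please", call. = FALSE)
  for (g in unique(expression$name)) {
    tt <- expression$time[expression$name == g]
    if (length(tt) < 2L)
      stop("genotype '", g, "': need at least two expression samples",
           call. = FALSE)
    if (any(diff(tt) <= 0))
      stop("genotype '", g, "': sampling times must be strictly increasing",
           call. = FALSE)
  }
  if (nrow(expression) &&
      (min(expression$rna) < 0 || max(expression$rna) > 1))
    stop("scaled expression must lie within [0, 1]; run scale_expression()",
         call. = FALSE)
  structure(list(expression = expression, dti = dti,
                 panel = panel[panel$name %in% obs_names, , drop = FALSE]),
            class = "dgn_observations")
}

#' @export
print.dgn_observations <- function(x, ...) {
  cat(sprintf(
    "DGN calibration observations: %d genotype(s), %d expression samples, %d DTI value(s)\n",
    nrow(x$panel), nrow(x$expression), nrow(x$dti)))
  invisible(x)
}

# Simulate one observed genotype, interpolate predictions at the sampling
# times, and return the predicted DTI (horizon failures become t_max so the
# objective stays finite and decreasing toward feasibility).
predict_for_genotype <- function(genotype, params, settings, at_times) {
  tr <- withCallingHandlers(
    dgn_simulate(genotype, params, settings),
    dgn_horizon_exhausted = function(w) invokeRestart("muffleWarning"))
  rna_pred <- if (length(at_times))
    stats::approx(tr$times, tr$mzmm4, xout = at_times, rule = 2)$y
  else numeric(0)
  list(rna_pred = rna_pred,
       dti_pred = if (tr$reached) tr$dti else settings$t_max,
       reached = tr$reached)
}

#' Combined expression-and-phenotype calibration objective
#'
#' The sum-of-squared-errors objective minimized during calibration:
#' \deqn{SSE_g = \sum_g \sum_i (RNAp_{g,i} - RNAo_{g,i})^2,\quad
#'       SSE_p = \sum_g (DTIp_g - DTIo_g)^2,\quad SSE = SSE_g + SSE_p.}
#' Predicted expression \eqn{RNAp} comes from the Euler trajectory,
#' linearly interpolated at the observed sampling times; predicted DTI is
#' the interpolated threshold crossing. The two components are summed with
#' unit weights despite their unit mismatch (squared scaled expression vs
#' squared days), matching the reference analysis; \code{weight_phenotype}
#' exposes the balance for sensitivity work. A genotype whose trajectory
#' never reaches the threshold contributes \code{t_max} as a finite
#' pessimistic surrogate DTI.
#'
#' @param params A \code{"dgn_params"} vector.
#' @param observations A \code{"dgn_observations"} object.
#' @param settings A \code{"dgn_settings"} list.
#' @param weight_phenotype Weight on \code{sse_p} in the total (default 1).
#' @return A list with components \code{sse_g}, \code{sse_p}, \code{sse}.
#' @export
dgn_objective <- function(params, observations, settings = dgn_settings(),
                          weight_phenotype = 1) {
  stopifnot(inherits(observations, "dgn_observations"))
  params <- as_dgn_params(params)
  sse_g <- 0
  sse_p <- 0
  for (g in observations$panel$name) {
    gt <- observations$panel[observations$panel$name == g, , drop = FALSE]
    ex <- observations$expression[observations$expression$name == g, ,
                                  drop = FALSE]
    pred <- tryCatch(
      predict_for_genotype(gt, params, settings, ex$time),
      error = function(e)
        stop("genotype '", g, "': ", conditionMessage(e), call. = FALSE))
    sse_g <- sse_g + sum((pred$rna_pred - ex$rna)^2)
    d <- observations$dti[observations$dti$name == g, , drop = FALSE]
    if (nrow(d)) sse_p <- sse_p + (pred$dti_pred - d$dti_obs)^2
  }
  sse_p <- as.numeric(sse_p)
  list(sse_g = sse_g, sse_p = sse_p,
       sse = sse_g + weight_phenotype * sse_p)
}

#' Optimizer configuration for model calibration
#'
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Relative convergence tolerance on the objective.
#' @param restarts Number of simplex restarts from the best point found;
#'   restarting rebuilds the simplex and guards against premature collapse.
#' @param log_space If \code{TRUE} (default) optimize the logarithms of the
#'   coefficients, which enforces positivity by construction.
#' @param weight_phenotype Passed to [dgn_objective()].
#' @return A list of class \code{"dgn_control"}.
#' @export
dgn_control <- function(maxit = 5000, reltol = 1e-10, restarts = 3,
                        log_space = TRUE, weight_phenotype = 1) {
  stopifnot(maxit >= 1, reltol > 0, restarts >= 0)
  structure(list(maxit = maxit, reltol = reltol, restarts = restarts,
                 log_space = log_space,
                 weight_phenotype = weight_phenotype),
            class = "dgn_control")
}

# Rank check on the regulatory design: the forcing constants are linear in
# (ID1, ID1*DLF1, VGT1, beta multiplier); separating alpha1, alpha2, alpha3
# and beta needs four independent rows across the observed genotypes.
dgn_design_rank <- function(panel) {
  X <- cbind(id1 = panel$id1,
             id1_dlf1 = panel$id1 * panel$dlf1,
             vgt1 = panel$vgt1,
             beta_mult = ifelse(panel$zmm4_transgene == 1, 2, 1))
  qr(X)$rank
}

#' Fit the dynamic gene network model
#'
#' Estimates the five model coefficients by minimizing the combined
#' expression + phenotype sum of squared errors ([dgn_objective()]) with
#' the Nelder-Mead downhill simplex method, by default on the log scale so
#' every candidate coefficient stays strictly positive. The optimizer is
#' restarted from its best point to rebuild the simplex; the whole
#' procedure is deterministic given the starting vector.
#'
#' Before fitting, the allele design of the observed genotypes is checked:
#' the genotype-specific forcing constants are linear in four regressors
#' (ID1, the ID1-by-DLF1 product, VGT1, and the basal-synthesis
#' multiplier), so the observed panel must span four independent allele
#' combinations for \code{alpha1}, \code{alpha2}, \code{alpha3} and
#' \code{beta} to be separable. A rank-deficient design is refused.
#'
#' @param observations A \code{"dgn_observations"} object.
#' @param start Starting coefficients (a \code{"dgn_params"} vector).
#' @param settings A \code{"dgn_settings"} list.
#' @param control A \code{"dgn_control"} list.
#' @return An object of class \code{"dgn_fit"} with components
#'   \code{params} (the estimate), \code{sse_g}, \code{sse_p}, \code{sse},
#'   \code{convergence} (\code{TRUE} if the final Nelder-Mead run reported
#'   convergence), \code{iterations} (total objective evaluations),
#'   \code{start}, \code{observations}, \code{settings}, \code{control}.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot}, \code{simulate}.
#' @examples
#' truth <- dgn_published_params()
#' panel <- dgn_example_panel(training = TRUE)
#' synth <- dgn_synthesize(truth, panel, rna_noise_sd = 0, dti_noise_sd = 0)
#' \donttest{
#' fit <- dgn_fit(synth$observations, start = dgn_perturb_start(truth))
#' coef(fit)
#' }
#' @export
dgn_fit <- function(observations, start,
                    settings = dgn_settings(), control = dgn_control()) {
  stopifnot(inherits(observations, "dgn_observations"),
            inherits(control, "dgn_control"))
  start <- as_dgn_params(start)
  rk <- dgn_design_rank(observations$panel)
  if (rk < 4L)
    stop("degenerate design: the observed genotypes span only ", rk,
         " independent allele combinations; alpha1, alpha2, alpha3 and ",
         "beta are not jointly identifiable (need 4)", call. = FALSE)

  to_opt <- if (control$log_space) log(unclass(start)) else unclass(start)
  fn <- function(theta) {
    p <- if (control$log_space) exp(theta) else theta
    if (any(!is.finite(p)) || any(p <= 0)) return(.Machine$double.xmax)
    dgn_objective(as_dgn_params(p), observations, settings,
                  control$weight_phenotype)$sse
  }
  total_evals <- 0L
  opt <- NULL
  for (r in seq_len(1L + control$restarts)) {
    opt <- stats::optim(to_opt, fn, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    total_evals <- total_evals + opt$counts[["function"]]
    to_opt <- opt$par
  }
  est <- as_dgn_params(if (control$log_space) exp(opt$par) else opt$par)
  parts <- dgn_objective(est, observations, settings,
                         control$weight_phenotype)
  converged <- opt$convergence == 0L
  if (!converged)
    warning(warningCondition(
      sprintf("Nelder-Mead did not meet tolerances (code %d); returning best point found (sse = %.6g)",
              opt$convergence, parts$sse),
      class = "dgn_nonconvergence"))
  structure(list(params = est, sse_g = parts$sse_g, sse_p = parts$sse_p,
                 sse = parts$sse, convergence = converged,
                 iterations = total_evals, start = start,
                 observations = observations, settings = settings,
                 control = control, call = match.call()),
            class = "dgn_fit")
}

#' Algebraic inversion of the training-panel forcing constants
#'
#' An exact identifiability oracle: given the genotype-specific forcing
#' constants of the four training genotypes (id1 mutant, dlf1 mutant, B73,
#' Gaspe Flint — none transgenic) the coefficients are recovered in closed
#' form:
#' \deqn{\alpha_1 = c_{dlf1} - c_{id1},\quad \beta = c_{id1}/\alpha_1,\quad
#'   \alpha_2 = (c_{B73} - c_{dlf1})/\alpha_1,\quad
#'   \alpha_3 = (c_{Gaspe} - c_{B73})/\alpha_1.}
#' Composing [regulatory_input()] with this inversion is the identity on
#' positive coefficient vectors. The constants must be strictly increasing
#' in the order id1 < dlf1 < B73 < Gaspe; equal or disordered constants
#' mean the spacing carries no information about a coefficient and are
#' rejected.
#'
#' @param c_id1,c_dlf1,c_b73,c_gaspe Forcing constants (per day) of the
#'   four training genotypes.
#' @param omega Feedback rate (per day), passed through.
#' @return A \code{"dgn_params"} vector.
#' @export
invert_closed_form <- function(c_id1, c_dlf1, c_b73, c_gaspe, omega) {
  cs <- c(c_id1, c_dlf1, c_b73, c_gaspe)
  if (any(diff(cs) <= 0))
    stop("degenerate forcing constants: need c_id1 < c_dlf1 < c_b73 < ",
         "c_gaspe for the inversion to be defined", call. = FALSE)
  alpha1 <- c_dlf1 - c_id1
  dgn_params(alpha1 = alpha1,
             alpha2 = (c_b73 - c_dlf1) / alpha1,
             alpha3 = (c_gaspe - c_b73) / alpha1,
             beta = c_id1 / alpha1,
             omega = omega)
}
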
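#' Generate a synthetic calibration/evaluation dataset
#'
#' Draws, for each genotype in the panel, a scaled ZMM4 expression time
#' series and an observed days-to-tassel-initiation (DTI) value from the
#' model itself, plus per-genotype total leaf number (TLN) means linked
#' linearly to DTI. The generator emulates the structure of the study's
#' greenhouse expression series and field TLN means, which were published
#' only graphically; it is the package's stand-in for those data, not a
#' reconstruction of them.
#'
#' Per genotype g with forcing constant \eqn{c_g}:
#' \itemize{
#'   \item sampling times: \code{n_times} evenly spaced points on
#'     \eqn{[0, t^*_g]}, where \eqn{t^*_g} is the analytic crossing time —
#'     a stylization of the study's genotype-dependent sampling cadence,
#'     which is not published;
#'   \item expression: the exact closed-form trajectory plus additive
#'     Gaussian noise (sd \code{rna_noise_sd}), clipped to [0, 1];
#'   \item observed DTI: \eqn{t^*_g} plus Gaussian noise
#'     (sd \code{dti_noise_sd});
#'   \item TLN: \code{tln_intercept + tln_slope * DTI} plus Gaussian noise
#'     (sd \code{tln_noise_sd}); negative draws are resampled. The default
#'     link (intercept 12 leaves, slope 0.35 leaves/day) puts B73
#'     (DTI about 21 d) near 19-20 leaves, a realistic temperate value;
#'     it is a fabricated calibration choice, not a measured relation.
#' }
#' Output is bit-reproducible for a fixed \code{seed}.
#'
#' @param truth Generating coefficients (a \code{"dgn_params"} vector).
#' @param panel A \code{"dgn_panel"}; every genotype must have a strictly
#'   positive forcing constant under \code{truth}.
#' @param n_times Samples per genotype (at least 2).
#' @param rna_noise_sd,dti_noise_sd,tln_noise_sd Gaussian noise standard
#'   deviations (scaled units, days, leaves); each must be non-negative.
#' @param tln_intercept,tln_slope TLN-DTI link (leaves; leaves/day,
#'   positive).
#' @param seed Integer seed.
#' @param settings A \code{"dgn_settings"} list (threshold defines the
#'   crossing).
#' @return A list of class \code{"dgn_synth"}: \code{observations} (a
#'   \code{"dgn_observations"}), \code{tln} (data frame \code{name},
#'   \code{tln}), \code{dti_true} (analytic crossing times), \code{truth},
#'   \code{seed}.
#' @examples
#' synth <- dgn_synthesize(dgn_published_params(),
#'                         dgn_example_panel(training = TRUE), seed = 7)
#' synth$observations
#' @export
dgn_synthesize <- function(truth, panel, n_times = 10,
                           rna_noise_sd = 0.02, dti_noise_sd = 0.5,
                           tln_intercept = 12, tln_slope = 0.35,
                           tln_noise_sd = 1, seed = 1L,
                           settings = dgn_settings()) {
  truth <- as_dgn_params(truth)
  panel <- as_dgn_panel(panel)
  stopifnot(n_times >= 2, rna_noise_sd >= 0, dti_noise_sd >= 0,
            tln_noise_sd >= 0, tln_slope > 0)
  c_g <- regulatory_input(panel, truth)
  if (any(c_g <= 0 & truth[["omega"]] == 0))
    stop("genotype(s) can never reach the threshold: ",
         paste(panel$name[c_g <= 0], collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  dti_true <- vapply(c_g, dgn_analytic_dti, numeric(1),
                     omega = truth[["omega"]],
                     threshold = settings$threshold)
  ex <- do.call(rbind, lapply(panel$name, function(g) {
    tt <- seq(0, dti_true[[g]], length.out = n_times)
    rna <- dgn_closed_form(c_g[[g]], truth[["omega"]], tt) /
      settings$threshold
    rna <- rna + stats::rnorm(n_times, sd = rna_noise_sd)
    data.frame(name = g, time = tt, rna = pmin(1, pmax(0, rna)))
  }))
  dti_obs <- data.frame(
    name = panel$name,
    dti_obs = unname(dti_true) + stats::rnorm(nrow(panel),
                                              sd = dti_noise_sd))
  tln <- generate_tln(unname(dti_true), tln_intercept, tln_slope,
                      tln_noise_sd)
  structure(list(
    observations = dgn_observations(ex, dti_obs, panel),
    tln = data.frame(name = panel$name, tln = tln),
    dti_true = dti_true, truth = truth, seed = as.integer(seed)),
    class = "dgn_synth")
}

# TLN = intercept + slope * DTI + Gaussian noise; negative draws are
# resampled (leaf counts are positive). Uses the current RNG stream.
generate_tln <- function(dti, intercept, slope, noise_sd) {
  mu <- intercept + slope * dti
  tln <- mu + stats::rnorm(length(dti), sd = noise_sd)
  for (i in seq_along(tln)) {
    while (tln[i] <= 0) tln[i] <- mu[i] + stats::rnorm(1, sd = noise_sd)
  }
  tln
}

#' TLN noise level implying a target regression R-squared
#'
#' Inverts the ordinary-least-squares R-squared relation
#' \eqn{R^2 = s^2_{fit}/(s^2_{fit} + \sigma^2)} for the noise standard
#' deviation: \eqn{\sigma = |slope|\, s_x \sqrt{(1 - R^2)/R^2}}, where
#' \eqn{s_x} is the sample standard deviation of the predicted DTI values
#' across the panel. Generating TLN with this noise makes the expected
#' realized R-squared of the TLN-on-DTI regression approximately the
#' requested value.
#'
#' @param dti Predicted DTI values across the panel (days).
#' @param slope TLN-DTI link slope (leaves/day).
#' @param r2 Target R-squared in (0, 1).
#' @return Noise standard deviation (leaves).
#' @export
tln_noise_for_r2 <- function(dti, slope, r2) {
  stopifnot(length(dti) >= 3, r2 > 0, r2 < 1)
  abs(slope) * stats::sd(dti) * sqrt((1 - r2) / r2)
}

#' @export
print.dgn_synth <- function(x, ...) {
  cat(sprintf("Synthetic DGN dataset (seed %d): %d genotypes, %d expression samples\n",
              x$seed, length(x$dti_true), nrow(x$observations$expression)))
  invisible(x)
}
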
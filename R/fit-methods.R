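#' @export
print.dgn_fit <- function(x, digits = 6, ...) {
  cat("Dynamic gene network model fit (Nelder-Mead)\n")
  cat("Coefficients:\n")
  print(round(unclass(x$params), digits))
  cat(sprintf("SSE = %.6g (expression %.6g + phenotype %.6g); %s after %d objective evaluations\n",
              x$sse, x$sse_g, x$sse_p,
              if (x$convergence) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.dgn_fit <- function(object, ...) unclass(object$params)

#' Predict days to tassel initiation for a genotype panel from a fit
#'
#' @param object A \code{"dgn_fit"}.
#' @param newdata A \code{"dgn_panel"} (defaults to the panel the model was
#'   fitted on).
#' @param ... Unused.
#' @return A data frame of prediction records: \code{name}, \code{dti},
#'   \code{reached}.
#' @export
predict.dgn_fit <- function(object, newdata = object$observations$panel,
                            ...) {
  dgn_predict_panel(newdata, object$params, object$settings)
}

#' @export
fitted.dgn_fit <- function(object, ...) {
  obs <- object$observations
  out <- obs$expression
  out$fitted <- NA_real_
  for (g in unique(out$name)) {
    gt <- obs$panel[obs$panel$name == g, , drop = FALSE]
    sel <- out$name == g
    out$fitted[sel] <- predict_for_genotype(gt, object$params,
                                            object$settings,
                                            out$time[sel])$rna_pred
  }
  out[c("name", "time", "fitted")]
}

#' Residuals of a dynamic gene network fit
#'
#' @param object A \code{"dgn_fit"}.
#' @param type \code{"expression"} for per-sample scaled-expression
#'   residuals (observed minus fitted), \code{"dti"} for per-genotype
#'   transition-time residuals (days).
#' @param ... Unused.
#' @return A data frame.
#' @export
residuals.dgn_fit <- function(object, type = c("expression", "dti"), ...) {
  type <- match.arg(type)
  obs <- object$observations
  if (type == "expression") {
    f <- fitted(object)
    data.frame(name = f$name, time = f$time,
               residual = obs$expression$rna - f$fitted)
  } else {
    pred <- predict(object)
    m <- merge(obs$dti, pred[c("name", "dti")], by = "name")
    data.frame(name = m$name, residual = m$dti_obs - m$dti)
  }
}

#' @export
summary.dgn_fit <- function(object, ...) {
  pred <- predict(object)
  dti_tab <- merge(object$observations$dti, pred[c("name", "dti")],
                   by = "name", all.x = TRUE)
  names(dti_tab) <- c("name", "observed", "predicted")
  dti_tab$residual <- dti_tab$observed - dti_tab$predicted
  res <- structure(list(params = object$params, sse_g = object$sse_g,
                        sse_p = object$sse_p, sse = object$sse,
                        convergence = object$convergence,
                        iterations = object$iterations,
                        n_expression = nrow(object$observations$expression),
                        dti_table = dti_tab),
                   class = "summary.dgn_fit")
  res
}

#' @export
print.summary.dgn_fit <- function(x, digits = 6, ...) {
  cat("Dynamic gene network model fit\n\nCoefficients:\n")
  print(round(unclass(x$params), digits))
  cat(sprintf("\nObjective: SSE = %.6g = SSEg %.6g (on %d expression samples) + SSEp %.6g\n",
              x$sse, x$sse_g, x$n_expression, x$sse_p))
  cat(sprintf("Optimizer: %s, %d objective evaluations\n\n",
              if (x$convergence) "converged" else "not converged",
              x$iterations))
  cat("Days to tassel initiation (per genotype):\n")
  print(x$dti_table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot observed vs fitted expression trajectories
#'
#' One panel per genotype: observed scaled ZMM4 samples (points) with the
#' fitted Euler trajectory (line) up to the predicted transition.
#'
#' @param x A \code{"dgn_fit"}.
#' @param ... Passed to \code{plot()}.
#' @export
plot.dgn_fit <- function(x, ...) {
  obs <- x$observations
  genos <- obs$panel$name
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(genos)))
  on.exit(graphics::par(op))
  for (g in genos) {
    gt <- obs$panel[obs$panel$name == g, , drop = FALSE]
    ex <- obs$expression[obs$expression$name == g, , drop = FALSE]
    tr <- withCallingHandlers(
      dgn_simulate(gt, x$params, x$settings),
      dgn_horizon_exhausted = function(w) invokeRestart("muffleWarning"))
    tmax <- if (tr$reached) tr$dti * 1.05 else x$settings$t_max
    keep <- tr$times <= tmax
    graphics::plot(tr$times[keep], tr$mzmm4[keep], type = "l",
                   xlab = "days after planting",
                   ylab = "scaled ZMM4 mRNA", main = g,
                   ylim = c(0, max(1, ex$rna)), ...)
    graphics::points(ex$time, ex$rna, pch = 15)
  }
  invisible(x)
}

#' Simulate synthetic calibration datasets from a fitted model
#'
#' Draws datasets from the generator with the fitted coefficients as
#' truth, using the fitted panel and the generator's default sampling
#' schedule and noise levels (overridable through \code{...}).
#'
#' @param object A \code{"dgn_fit"}.
#' @param nsim Number of datasets.
#' @param seed Integer seed; replicate r uses \code{seed + r - 1}.
#' @param ... Passed to [dgn_synthesize()].
#' @return A list of \code{nsim} synthetic datasets (see
#'   [dgn_synthesize()]); a single dataset if \code{nsim = 1}.
#' @export
simulate.dgn_fit <- function(object, nsim = 1, seed = 1L, ...) {
  sims <- lapply(seq_len(nsim), function(r)
    dgn_synthesize(object$params, object$observations$panel,
                   seed = seed + r - 1L, settings = object$settings, ...))
  if (nsim == 1L) sims[[1L]] else sims
}
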
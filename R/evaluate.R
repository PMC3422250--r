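#' Predict days to tassel initiation for every genotype in a panel
#'
#' Runs the Euler simulation for each genotype and collects the predicted
#' transition times. Transgenic lines are handled through the doubled
#' basal-synthesis rule inside [regulatory_input()]. A genotype whose
#' trajectory never reaches the threshold within the horizon is reported
#' with \code{dti = NA} and \code{reached = FALSE}; the remaining
#' genotypes are still returned.
#'
#' @param panel A \code{"dgn_panel"}.
#' @param params A \code{"dgn_params"} vector.
#' @param settings A \code{"dgn_settings"} list.
#' @return A data frame of prediction records: \code{name}, \code{dti}
#'   (days), \code{reached} (logical).
#' @examples
#' dgn_predict_panel(dgn_example_panel(), dgn_published_params())
#' @export
dgn_predict_panel <- function(panel, params, settings = dgn_settings()) {
  panel <- as_dgn_panel(panel)
  if (!nrow(panel)) stop("empty genotype panel", call. = FALSE)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    tr <- withCallingHandlers(
      dgn_simulate(panel[i, , drop = FALSE], params, settings),
      dgn_horizon_exhausted = function(w) invokeRestart("muffleWarning"))
    data.frame(name = panel$name[i], dti = tr$dti, reached = tr$reached)
  })
  out <- do.call(rbind, rows)
  if (any(!out$reached))
    warning(warningCondition(
      paste0("threshold not reached within the horizon for: ",
             paste(out$name[!out$reached], collapse = ", ")),
      class = "dgn_horizon_exhausted"))
  out
}

#' Regress observed total leaf number on predicted transition time
#'
#' Ordinary least squares of per-genotype mean TLN (response) on predicted
#' DTI (regressor) — the model's evaluation step: leaf initiation stops at
#' the floral transition, so total leaf number is a stable field proxy for
#' the transition time, and a strong linear relation indicates the model
#' ranks and spaces genotypes correctly. Genotype means, not per-plant
#' values, are regressed.
#'
#' @param predictions Data frame with columns \code{name}, \code{dti}
#'   (e.g. from [dgn_predict_panel()]); rows with \code{NA} DTI are
#'   dropped.
#' @param tln Data frame with columns \code{name}, \code{tln} (leaves).
#' @return A list of class \code{"dgn_regression"}: \code{slope}
#'   (leaves/day), \code{intercept} (leaves), \code{r_squared}, \code{n},
#'   \code{model} (the underlying \code{lm} fit), \code{data} (the merged
#'   scatter table).
#' @export
tln_dti_regression <- function(predictions, tln) {
  stopifnot(all(c("name", "dti") %in% names(predictions)),
            all(c("name", "tln") %in% names(tln)))
  d <- merge(predictions[c("name", "dti")], tln[c("name", "tln")],
             by = "name")
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3)
    stop("need at least 3 genotypes with both TLN and predicted DTI",
         call. = FALSE)
  if (stats::var(d$dti) == 0)
    stop("degenerate regressor: all predicted DTI values are equal",
         call. = FALSE)
  fit <- stats::lm(tln ~ dti, data = d)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$tln - mean(d$tln))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[["dti"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = r2, n = nrow(d), model = fit, data = d),
            class = "dgn_regression")
}

#' @export
print.dgn_regression <- function(x, ...) {
  cat(sprintf("TLN ~ predicted DTI (n = %d genotypes)\n", x$n))
  cat(sprintf("  TLN = %.3f + %.4f * DTI,  R^2 = %.3f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
plot.dgn_regression <- function(x, ...) {
  graphics::plot(x$data$dti, x$data$tln,
                 xlab = "predicted DTI (days)",
                 ylab = "observed TLN (leaves)", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Check the qualitative genotype ordering of transition times
#'
#' Verifies the orderings the model must reproduce for the training panel:
#' Gaspe Flint (early VGT1 allele) transitions first, then B73, then the
#' \emph{dlf1} mutant, with the \emph{id1} mutant last (losing ID1 removes
#' both ID1-dependent terms); and the \emph{id1 dlf1} double mutant is
#' indistinguishable from the \emph{id1} single mutant, since ID1 = 0
#' already annihilates the ID1-by-DLF1 interaction. Record order is
#' irrelevant. Ties are reported as failures of the strict comparisons.
#'
#' @param predictions Data frame with columns \code{name}, \code{dti};
#'   must contain GaspeFlint, B73, dlf1 and id1 (id1_dlf1 optional).
#' @return A named logical vector, one element per comparison, with
#'   attribute \code{"missing"} listing absent genotypes.
#' @export
check_ordering <- function(predictions) {
  stopifnot(all(c("name", "dti") %in% names(predictions)))
  need <- c("GaspeFlint", "B73", "dlf1", "id1")
  missing <- setdiff(need, predictions$name)
  if (length(missing))
    stop("ordering check needs the training genotypes; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  dti <- stats::setNames(predictions$dti, predictions$name)
  out <- c("GaspeFlint<B73" = unname(dti["GaspeFlint"] < dti["B73"]),
           "B73<dlf1" = unname(dti["B73"] < dti["dlf1"]),
           "dlf1<=id1" = unname(dti["dlf1"] <= dti["id1"]))
  if ("id1_dlf1" %in% predictions$name)
    out <- c(out, "id1==id1_dlf1" =
               isTRUE(all.equal(unname(dti["id1"]),
                                unname(dti["id1_dlf1"]))))
  attr(out, "missing") <- character(0)
  out
}
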
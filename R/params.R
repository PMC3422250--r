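#' Model coefficients of the dynamic gene network
#'
#' The five coefficients of the ZMM4 expression equation
#' \deqn{dm/dt = \alpha_1 (ID1 + \alpha_2\, ID1\cdot DLF1 + \alpha_3\, VGT1
#'   + \beta_{eff}) + \omega\, m}
#' where \eqn{\beta_{eff} = \beta} (or \eqn{2\beta} for a line carrying the
#' ZMM4 overexpression transgene). \code{alpha1} is a global scaling factor
#' (per day, on scaled-expression units); \code{alpha2} weights the
#' ID1-by-DLF1 interaction (the florigen–DLF1 protein-complex path);
#' \code{alpha3} weights the early VGT1 allele; \code{beta} is the basal
#' ZMM4 synthesis weight; \code{omega} (per day) is the positive-feedback
#' rate. All five must be strictly positive — the model describes
#' accumulation toward the floral transition and is meaningless for
#' negative rates.
#'
#' @param alpha1,alpha2,alpha3,beta,omega Strictly positive coefficients.
#' @return A named numeric vector of class \code{"dgn_params"}.
#' @examples
#' dgn_params(0.002, 6.489431, 53.204799, 0.821720, 0.086782)
#' @seealso [dgn_published_params()]
#' @export
dgn_params <- function(alpha1, alpha2, alpha3, beta, omega) {
  p <- c(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
         beta = beta, omega = omega)
  as_dgn_params(p)
}

#' @rdname dgn_params
#' @param x A named numeric vector with elements
#'   \code{alpha1, alpha2, alpha3, beta, omega}.
#' @export
as_dgn_params <- function(x) {
  nm <- c("alpha1", "alpha2", "alpha3", "beta", "omega")
  if (!is.numeric(x) || !all(nm %in% names(x)))
    stop("parameters must be a named numeric vector with elements ",
         paste(nm, collapse = ", "), call. = FALSE)
  p <- unclass(x)[nm]
  if (anyNA(p) || any(p <= 0))
    stop("all five model coefficients must be strictly positive",
         call. = FALSE)
  structure(p, class = "dgn_params")
}

#' Published point estimates of the model coefficients
#'
#' The reference fitted coefficient vector, estimated from scaled ZMM4
#' expression and observed transition times of the four training genotypes
#' (Gaspe Flint, B73, dlf1, id1). Used as the generating truth in
#' parameter-recovery experiments.
#'
#' @return A \code{"dgn_params"} vector.
#' @export
dgn_published_params <- function() {
  read_param_table(system.file("extdata", "published_params.tsv",
                               package = "dgnmaize", mustWork = TRUE))
}

#' @export
print.dgn_params <- function(x, digits = 6, ...) {
  cat("DGN model coefficients:\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Default perturbed optimizer start
#'
#' Perturbs each coefficient multiplicatively, alternating +50% and -33%
#' across coordinates. This is the default starting point for
#' parameter-recovery fits: far enough from the generating values to
#' exercise the optimizer, close enough to stay in the model's plausible
#' range.
#'
#' @param params A \code{"dgn_params"} vector.
#' @param factors Multiplicative perturbation per coordinate, recycled.
#' @return A \code{"dgn_params"} vector.
#' @export
dgn_perturb_start <- function(params, factors = c(1.5, 2 / 3)) {
  params <- as_dgn_params(params)
  as_dgn_params(unclass(params) * rep_len(factors, length(params)))
}
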
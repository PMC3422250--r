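#' Define a maize genotype by its binary allele states
#'
#' A genotype is encoded by the presence (1) or absence (0) of the functional
#' alleles of three flowering-time genetic elements — \emph{VGT1} (1 = the
#' early Gaspe Flint allele), \emph{ID1} and \emph{DLF1} — plus a flag for a
#' constitutively overexpressed \emph{ZMM4} transgene. The native \emph{ZMM4}
#' copy is always present and is not stored.
#'
#' @param name Genotype label (unique within a panel).
#' @param vgt1,id1,dlf1 Binary allele states, each exactly 0 or 1.
#' @param zmm4_transgene Binary flag; 1 doubles the basal synthesis
#'   coefficient \eqn{\beta} in the regulatory input (two gene copies).
#' @return An object of class \code{"dgn_genotype"}: a one-row data frame
#'   with columns \code{name}, \code{vgt1}, \code{id1}, \code{dlf1},
#'   \code{zmm4_transgene}.
#' @examples
#' dgn_genotype("B73", vgt1 = 0, id1 = 1, dlf1 = 1)
#' @seealso [dgn_panel()], [dgn_example_panel()]
#' @export
dgn_genotype <- function(name, vgt1, id1, dlf1, zmm4_transgene = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in list(vgt1 = vgt1, id1 = id1, dlf1 = dlf1,
                 zmm4_transgene = zmm4_transgene)) {
    if (length(v) != 1L || is.na(v) || !v %in% c(0, 1))
      stop("allele states and the transgene flag must each be exactly 0 or 1",
           call. = FALSE)
  }
  g <- data.frame(name = name, vgt1 = as.integer(vgt1), id1 = as.integer(id1),
                  dlf1 = as.integer(dlf1),
                  zmm4_transgene = as.integer(zmm4_transgene),
                  stringsAsFactors = FALSE)
  class(g) <- c("dgn_genotype", "dgn_panel", "data.frame")
  g
}

#' Assemble a genotype panel
#'
#' Binds genotypes into a panel (one row per genotype) and validates it:
#' every allele field must be 0/1 and names must be unique.
#'
#' @param ... \code{dgn_genotype} objects, or data frames with the panel
#'   columns \code{name}, \code{vgt1}, \code{id1}, \code{dlf1},
#'   \code{zmm4_transgene}.
#' @return A \code{"dgn_panel"} data frame.
#' @export
dgn_panel <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1L]])) parts <- parts[1L]
  df <- do.call(rbind, lapply(parts, as.data.frame))
  as_dgn_panel(df)
}

#' @rdname dgn_panel
#' @param x A data frame to validate and classify as a genotype panel.
#' @export
as_dgn_panel <- function(x) {
  req <- c("name", "vgt1", "id1", "dlf1", "zmm4_transgene")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)[req]
  x$name <- as.character(x$name)
  if (anyDuplicated(x$name))
    stop("genotype names must be unique within a panel; duplicated: ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "),
         call. = FALSE)
  for (col in req[-1L]) {
    v <- x[[col]]
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("column '", col, "' must contain only 0 or 1", call. = FALSE)
    x[[col]] <- as.integer(v)
  }
  rownames(x) <- NULL
  class(x) <- c("dgn_panel", "data.frame")
  x
}

#' The eight-genotype study panel
#'
#' The panel used throughout the package: the B73 inbred, the late-flowering
#' \emph{id1} and \emph{dlf1} single mutants, the early Gaspe Flint landrace
#' (carrying the early \emph{VGT1} allele), the \emph{id1 dlf1} double
#' mutant, and \emph{ZMM4}-overexpressing transgenic lines in the B73,
#' \emph{id1} and \emph{dlf1} backgrounds.
#'
#' The published allele table lists the transgenic \emph{id1} line with
#' ID1 = 1, DLF1 = 0 and the transgenic \emph{dlf1} line with ID1 = 0,
#' DLF1 = 1 — the reverse of what the genotype names imply (an apparent
#' column swap). The default \code{"name_consistent"} variant derives allele
#' states from the names (an \emph{id1} background has ID1 = 0); the
#' \code{"as_printed"} variant reproduces the published rows verbatim.
#'
#' @param variant Which encoding of the two transgenic mutant lines to use.
#' @param training If \code{TRUE}, return only the four genotypes used for
#'   calibration (GaspeFlint, B73, dlf1, id1).
#' @return A \code{"dgn_panel"} data frame.
#' @examples
#' dgn_example_panel(training = TRUE)
#' @export
dgn_example_panel <- function(variant = c("name_consistent", "as_printed"),
                              training = FALSE) {
  variant <- match.arg(variant)
  file <- if (variant == "name_consistent") "genotypes.tsv" else
    "genotypes_as_printed.tsv"
  panel <- read_genotype_table(system.file("extdata", file,
                                           package = "dgnmaize",
                                           mustWork = TRUE))
  if (training)
    panel <- panel[panel$name %in% c("GaspeFlint", "B73", "dlf1", "id1"), ]
  as_dgn_panel(panel)
}

#' The simplified regulatory topology behind the model
#'
#' Signed edge list of the four-gene subnetwork the model condenses:
#' ID1 activates ZCN8 (the maize florigen candidate), ZCN8 and DLF1 jointly
#' activate ZMM4, VGT1 represses ZmRAP2.7 which represses ZMM4 (a double
#' repression collapsed to a positive VGT1 term), and ZMM4 carries a
#' proposed positive self-loop. Documentation resource only — the dynamics
#' use the collapsed logic-gated equation, not this edge list.
#'
#' @return A data frame with columns \code{source}, \code{target},
#'   \code{sign} (\code{"+"}/\code{"-"}) and \code{evidence}.
#' @export
dgn_grn_edges <- function() {
  utils::read.delim(system.file("extdata", "grn_edges.tsv",
                                package = "dgnmaize", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
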
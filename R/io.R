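## Tab-separated tables (header row, UTF-8, '.' decimal) are the exchange
## format for every pipeline stage; they are diff-friendly and mirror the
## tabular structure of the study's genotype and coefficient tables.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

# data line i of a TSV sits on file line i + 1 (header)
bad_rows <- function(path, which) {
  paste0(path, " line(s) ", paste(which + 1L, collapse = ", "))
}

#' Read a genotype panel from TSV
#'
#' Expects columns \code{name}, \code{vgt1}, \code{id1}, \code{dlf1},
#' \code{zmm4_transgene}; allele fields must be 0/1. Malformed rows are
#' reported with their file line numbers.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A \code{"dgn_panel"} data frame.
#' @export
read_genotype_table <- function(path) {
  req <- c("name", "vgt1", "id1", "dlf1", "zmm4_transgene")
  df <- read_tsv_checked(path, req)
  for (col in req[-1L]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !v %in% c(0, 1))
    if (length(bad))
      stop("non-binary '", col, "' value at ", bad_rows(path, bad),
           call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  as_dgn_panel(df)
}

#' Read a model coefficient table from TSV
#'
#' Expects columns \code{parameter}, \code{value} with one row for each of
#' \code{alpha1}, \code{alpha2}, \code{alpha3}, \code{beta}, \code{omega}.
#' A missing coefficient row is reported by name.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A \code{"dgn_params"} vector.
#' @export
read_param_table <- function(path) {
  df <- read_tsv_checked(path, c("parameter", "value"))
  nm <- c("alpha1", "alpha2", "alpha3", "beta", "omega")
  missing_rows <- setdiff(nm, df$parameter)
  if (length(missing_rows))
    stop(path, ": missing parameter row(s): ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  v <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(v))
  if (length(bad))
    stop("non-numeric value at ", bad_rows(path, bad), call. = FALSE)
  as_dgn_params(stats::setNames(v, df$parameter)[nm])
}

#' Read expression observations / DTI observations / TLN means from TSV
#'
#' \code{read_observation_table} expects \code{name}, \code{time},
#' \code{rna} (long format, scaled expression); \code{read_dti_table}
#' expects \code{name}, \code{dti_obs}; \code{read_tln_table} expects
#' \code{name}, \code{tln}. Non-numeric entries are reported with their
#' file line numbers.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame.
#' @export
read_observation_table <- function(path) {
  df <- read_tsv_checked(path, c("name", "time", "rna"))
  for (col in c("time", "rna")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric '", col, "' at ", bad_rows(path, bad),
           call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' @rdname read_observation_table
#' @export
read_dti_table <- function(path) {
  df <- read_tsv_checked(path, c("name", "dti_obs"))
  v <- suppressWarnings(as.numeric(df$dti_obs))
  bad <- which(is.na(v))
  if (length(bad))
    stop("non-numeric 'dti_obs' at ", bad_rows(path, bad), call. = FALSE)
  df$dti_obs <- v
  df
}

#' @rdname read_observation_table
#' @export
read_tln_table <- function(path) {
  df <- read_tsv_checked(path, c("name", "tln"))
  v <- suppressWarnings(as.numeric(df$tln))
  bad <- which(is.na(v))
  if (length(bad))
    stop("non-numeric 'tln' at ", bad_rows(path, bad), call. = FALSE)
  df$tln <- v
  df
}

# Atomic TSV writer: write to a sibling temp file, then rename into place.
write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a coefficient vector as TSV
#'
#' @param params A \code{"dgn_params"} vector.
#' @param path Output path.
#' @export
write_param_table <- function(params, path) {
  params <- as_dgn_params(params)
  write_tsv_atomic(data.frame(parameter = names(params),
                              value = sprintf("%.6f", unclass(params))),
                   path)
}

#' Run one pipeline stage end to end
#'
#' File-based front end binding the package's functions into four stages.
#' Each stage reads the TSV inputs named in \code{config}, runs the
#' corresponding functions, writes its outputs atomically under
#' \code{out_prefix}, and records a machine-readable \code{manifest.json}
#' (stage, input paths, settings, seed, output paths, package and R
#' versions) so a run can be reproduced exactly.
#'
#' Stages and their \code{config} entries (paths unless noted;
#' \code{genotypes} and \code{params} default to the shipped study
#' fixtures):
#' \describe{
#'   \item{\code{"simulate"}}{\code{genotypes}, \code{params}; writes
#'     per-genotype trajectories (\code{trajectories.tsv}: name, time,
#'     mzmm4, fts; times reported to 0.01 d) and a DTI summary
#'     (\code{dti.tsv}).}
#'   \item{\code{"synth"}}{\code{params} (generating truth),
#'     \code{genotypes}, \code{seed} (integer), plus optional generator
#'     settings (\code{n_times}, \code{rna_noise_sd}, \code{dti_noise_sd},
#'     \code{tln_intercept}, \code{tln_slope}, \code{tln_noise_sd});
#'     writes \code{observations.tsv}, \code{dti_obs.tsv}, \code{tln.tsv}
#'     and the truth table.}
#'   \item{\code{"fit"}}{\code{observations}, \code{dti},
#'     \code{genotypes}, \code{start} (coefficient TSV); writes
#'     \code{estimated_params.tsv} and \code{fit.json} diagnostics
#'     (sse_g, sse_p, sse, iterations, convergence).}
#'   \item{\code{"evaluate"}}{\code{genotypes}, \code{params},
#'     \code{tln}; writes \code{regression.json} and the merged scatter
#'     table \code{scatter.tsv}.}
#' }
#' Simulation settings (\code{dt}, \code{t_max}, \code{m0},
#' \code{threshold}) may be overridden in \code{config} for any stage.
#'
#' @param stage One of \code{"simulate"}, \code{"fit"}, \code{"synth"},
#'   \code{"evaluate"}.
#' @param config Named list of input paths and overrides (see above).
#' @param out_prefix Output directory (created if needed).
#' @return Invisibly, a named list of written file paths (including the
#'   manifest).
#' @export
dgn_run <- function(stage = c("simulate", "fit", "synth", "evaluate"),
                    config = list(), out_prefix = ".") {
  stage <- match.arg(stage)
  cfg_path <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  settings <- dgn_settings(
    dt = cfg_path("dt", 0.01), t_max = cfg_path("t_max", 100),
    m0 = cfg_path("m0", 0), threshold = cfg_path("threshold", 1))
  genotypes_path <- cfg_path(
    "genotypes", system.file("extdata", "genotypes.tsv",
                             package = "dgnmaize", mustWork = TRUE))
  params_path <- cfg_path(
    "params", system.file("extdata", "published_params.tsv",
                          package = "dgnmaize", mustWork = TRUE))
  dir.create(out_prefix, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_prefix, f)
  inputs <- list(genotypes = genotypes_path)
  written <- list()

  if (stage == "simulate") {
    panel <- read_genotype_table(genotypes_path)
    params <- read_param_table(params_path)
    inputs$params <- params_path
    traj <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
      tr <- withCallingHandlers(
        dgn_simulate(panel[i, , drop = FALSE], params, settings),
        dgn_horizon_exhausted = function(w) invokeRestart("muffleWarning"))
      data.frame(name = panel$name[i], time = sprintf("%.2f", tr$times),
                 mzmm4 = tr$mzmm4, fts = tr$fts)
    }))
    pred <- dgn_predict_panel(panel, params, settings)
    written$trajectories <- write_tsv_atomic(traj, out("trajectories.tsv"))
    written$dti <- write_tsv_atomic(
      data.frame(name = pred$name, dti = sprintf("%.2f", pred$dti)),
      out("dti.tsv"))
  } else if (stage == "synth") {
    panel <- read_genotype_table(genotypes_path)
    truth <- read_param_table(params_path)
    inputs$params <- params_path
    synth <- dgn_synthesize(
      truth, panel,
      n_times = cfg_path("n_times", 10),
      rna_noise_sd = cfg_path("rna_noise_sd", 0.02),
      dti_noise_sd = cfg_path("dti_noise_sd", 0.5),
      tln_intercept = cfg_path("tln_intercept", 12),
      tln_slope = cfg_path("tln_slope", 0.35),
      tln_noise_sd = cfg_path("tln_noise_sd", 1),
      seed = cfg_path("seed", 1L), settings = settings)
    written$observations <- write_tsv_atomic(
      synth$observations$expression, out("observations.tsv"))
    written$dti_obs <- write_tsv_atomic(synth$observations$dti,
                                        out("dti_obs.tsv"))
    written$tln <- write_tsv_atomic(synth$tln, out("tln.tsv"))
    written$truth <- write_param_table(truth, out("truth_params.tsv"))
  } else if (stage == "fit") {
    panel <- read_genotype_table(genotypes_path)
    obs_path <- cfg_path("observations")
    dti_path <- cfg_path("dti")
    start_path <- cfg_path("start", params_path)
    if (is.null(obs_path) || is.null(dti_path))
      stop("fit stage needs 'observations' and 'dti' paths in config",
           call. = FALSE)
    inputs$observations <- obs_path
    inputs$dti <- dti_path
    inputs$start <- start_path
    obs <- dgn_observations(read_observation_table(obs_path),
                            read_dti_table(dti_path), panel)
    fit <- dgn_fit(obs, start = read_param_table(start_path),
                   settings = settings)
    written$params <- write_param_table(fit$params,
                                        out("estimated_params.tsv"))
    written$diagnostics <- write_json_atomic(
      list(sse_g = fit$sse_g, sse_p = fit$sse_p, sse = fit$sse,
           iterations = fit$iterations, convergence = fit$convergence),
      out("fit.json"))
    if (!fit$convergence)
      warning(warningCondition("fit stage finished without convergence",
                               class = "dgn_nonconvergence"))
  } else { # evaluate
    panel <- read_genotype_table(genotypes_path)
    params <- read_param_table(params_path)
    tln_path <- cfg_path("tln")
    if (is.null(tln_path))
      stop("evaluate stage needs a 'tln' path in config", call. = FALSE)
    inputs$params <- params_path
    inputs$tln <- tln_path
    pred <- dgn_predict_panel(panel, params, settings)
    reg <- tln_dti_regression(pred, read_tln_table(tln_path))
    written$regression <- write_json_atomic(
      list(slope = reg$slope, intercept = reg$intercept,
           r_squared = reg$r_squared, n = reg$n),
      out("regression.json"))
    written$scatter <- write_tsv_atomic(reg$data, out("scatter.tsv"))
  }

  manifest <- list(
    stage = stage, inputs = inputs,
    settings = unclass(settings),
    seed = cfg_path("seed", NULL),
    outputs = lapply(written, as.character),
    package = "dgnmaize",
    package_version = as.character(utils::packageVersion("dgnmaize")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  written$manifest <- write_json_atomic(manifest, out("manifest.json"))
  invisible(written)
}
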
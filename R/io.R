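#' Write a study to plain-text files
#'
#' Serializes a `jnd_study` into a directory:
#' \describe{
#'   \item{`trials.csv`}{participant, block, trial, onset, magnitude_A,
#'     duration, true_net_w_kg, response (empty on first trials).}
#'   \item{`breaths.csv`}{participant, block, trial, t_s, power_w_kg.}
#'   \item{`standing.csv`}{participant, t_s, power_w_kg.}
#'   \item{`truth.json`}{per-participant ground truth and the generator
#'     config and seed.}
#' }
#' Real (non-synthetic) data in the same CSV schema can be read back with
#' [read_study()]; `truth.json` is then simply absent.
#'
#' @param study A `jnd_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "jnd_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$breaths, file.path(dir, "breaths.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$standing, file.path(dir, "standing.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(truth = study$truth, config = unclass(study$config),
         seed = study$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

read_numeric_csv <- function(path, required, na_ok = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(basename(path), ": missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in required) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !(is.na(v) | v == "" | v == "NA"))
    if (length(bad)) {
      stop(basename(path), ": non-numeric value in column '", col,
           "', row ", bad[1])
    }
    na_rows <- which(is.na(num))
    if (length(na_rows) && !(col %in% na_ok)) {
      stop(basename(path), ": missing value in column '", col,
           "', row ", na_rows[1])
    }
    df[[col]] <- num
  }
  df
}

#' Read a study from a directory of CSV files
#'
#' Inverse of [write_study()]. Performs schema validation with row-level
#' error messages: missing columns, non-numeric cells, duplicate
#' (participant, block, trial) keys, and responses that are absent on a
#' non-first trial (or present on a first trial) all fail loudly. If
#' `truth.json` is present the ground truth and generator config are
#' restored and the full study-level invariants are re-asserted.
#'
#' @param dir Directory containing `trials.csv`, `breaths.csv`,
#'   `standing.csv`, and optionally `truth.json`.
#' @return A `jnd_study` (with `truth`/`config` set to `NULL` when no
#'   `truth.json` exists).
#' @export
read_study <- function(dir) {
  trials <- read_numeric_csv(
    file.path(dir, "trials.csv"),
    c("participant", "block", "trial", "onset", "magnitude_A", "duration",
      "true_net_w_kg", "response"),
    na_ok = "response")
  breaths <- read_numeric_csv(
    file.path(dir, "breaths.csv"),
    c("participant", "block", "trial", "t_s", "power_w_kg"))
  standing <- read_numeric_csv(
    file.path(dir, "standing.csv"), c("participant", "t_s", "power_w_kg"))

  key <- paste(trials$participant, trials$block, trials$trial)
  dup <- which(duplicated(key))
  if (length(dup)) stop("trials.csv: duplicate (participant, block, trial) key, row ", dup[1])
  first <- trials$trial == 1
  bad_first <- which(first & !is.na(trials$response))
  if (length(bad_first)) {
    stop("trials.csv: response present on first trial of a block, row ", bad_first[1])
  }
  bad_resp <- which(!first & is.na(trials$response))
  if (length(bad_resp)) {
    stop("trials.csv: missing response in column 'response', row ", bad_resp[1])
  }
  trials$response <- as.integer(trials$response)

  truth <- NULL; config <- NULL; seed <- NA_integer_
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- as.data.frame(tj$truth)
    config <- do.call(study_config, tj$config)
    seed <- as.integer(tj$seed)
  }
  study <- structure(list(trials = trials, breaths = breaths,
                          standing = standing, truth = truth,
                          config = config, seed = seed),
                     class = "jnd_study")
  if (!is.null(config)) validate_study(study)
  study
}

#' Write comparisons to CSV
#'
#' @param comparisons A comparisons data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  utils::write.csv(comparisons, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read comparisons from CSV
#'
#' @param path CSV written by [write_comparisons()].
#' @return A `jnd_comparisons` data frame.
#' @export
read_comparisons <- function(path) {
  df <- read_numeric_csv(
    path, c("participant", "block", "pair", "A_w_kg", "B_w_kg",
            "x_percent", "response"))
  if (!all(df$response %in% c(0, 1))) stop(basename(path), ": responses must be 0/1")
  df$response <- as.integer(df$response)
  class(df) <- c("jnd_comparisons", "data.frame")
  df
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: generate (or accept) a study, estimate per-trial net
#' steady-state rates from the breath series, build sequential comparisons,
#' fit the pooled, independent and variable-WF models, compare them by
#' WAIC, and summarize the cohort (mean/SD/SE, KS normality check,
#' perception probabilities at the requested rate changes). Stage progress
#' and bookkeeping counts are reported via `message()`.
#'
#' @param config A [study_config()] used when `study` is not supplied.
#' @param seed Integer seed governing generation and all MCMC fits.
#' @param study Optional pre-built or ingested `jnd_study`; when supplied,
#'   `config` is ignored for generation.
#' @param mcmc MCMC settings for the independent and variable-WF models.
#' @param mcmc_pooled MCMC settings for the pooled model.
#' @param prior JND prior shared by all three models.
#' @param deltas Percent rate changes at which to evaluate the cohort
#'   perception probability (default 9.6).
#' @param out_dir Optional directory; when given, the study, comparisons,
#'   posterior draws and `results.json` are written there.
#' @return A list of class `jnd_pipeline`: `study`, `trials` (with rate
#'   estimates), `comparisons`, `fits` (three `jnd_fit`s), `waic_table`,
#'   `cohort`, `normality`, `perception` and the settings used.
#' @export
run_pipeline <- function(config = study_config(), seed = 1, study = NULL,
                         mcmc = mcmc_settings(), mcmc_pooled =
                           mcmc_settings(chains = 4, tune = 2000, draws = 2000),
                         prior = jnd_prior(), deltas = 9.6, out_dir = NULL) {
  t0 <- Sys.time()
  if (is.null(study)) {
    message("stage simulate: generating study (seed ", seed, ")")
    study <- generate_study(config, seed = seed)
  }
  message("stage metabolics: fitting ", nrow(study$trials),
          " trial transients")
  trials <- estimate_trial_rates(study)
  comparisons <- build_comparisons(trials)
  message("stage metabolics: ", nrow(comparisons), " comparisons (",
          attr(comparisons, "n_dropped"), " dropped)")

  message("stage fit: independent model")
  fit_ind <- fit_independent(comparisons, prior = prior, mcmc = mcmc,
                             seed = seed)
  message("stage fit: pooled model")
  fit_pool <- fit_pooled(comparisons, prior = prior, mcmc = mcmc_pooled,
                         seed = seed)
  message("stage fit: variable-WF model")
  fit_var <- fit_variable_wf(comparisons, prior = prior, mcmc = mcmc,
                             seed = seed)

  message("stage compare: WAIC")
  waics <- lapply(list(pooled = fit_pool, independent = fit_ind,
                       variable_wf = fit_var),
                  function(f) compute_waic(pointwise_loglik(f, comparisons)))
  waic_table <- compare_models(waics)

  est <- point_estimates(fit_ind)
  cohort <- summarize_cohort(est)
  normality <- if (length(est) >= 5 && stats::sd(est) > 0) {
    ks_normality(est)
  } else {
    list(statistic = NA_real_, p_value = NA_real_,
         note = "cohort too small (or degenerate) for the KS check")
  }
  perception <- data.frame(
    delta_percent = deltas,
    probability = vapply(deltas, function(d)
      perceive_probability(cohort$mean_jnd, d), numeric(1)))

  result <- structure(
    list(study = study, trials = trials, comparisons = comparisons,
         fits = list(independent = fit_ind, pooled = fit_pool,
                     variable_wf = fit_var),
         waic_table = waic_table, cohort = cohort, normality = normality,
         perception = perception,
         settings = list(seed = as.integer(seed), prior = unclass(prior),
                         mcmc = unclass(mcmc),
                         mcmc_pooled = unclass(mcmc_pooled)),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "jnd_pipeline")
  if (!is.null(out_dir)) write_results(result, out_dir)
  message(sprintf("pipeline complete in %.1f s", result$elapsed_s))
  result
}

#' Write pipeline results to disk
#'
#' Writes the study CSVs, `comparisons.csv`, per-participant posterior draws
#' (`posteriors/<participant>_<model>.csv`) and a `results.json` holding
#' point estimates, credible intervals, diagnostics, the WAIC table, the
#' cohort summary and the full settings echo (seed included), so a cohort
#' report can be regenerated from the directory alone.
#'
#' @param result A `jnd_pipeline`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "jnd_pipeline"))
  dir.create(file.path(dir, "posteriors"), recursive = TRUE,
             showWarnings = FALSE)
  write_study(result$study, dir)
  write_comparisons(result$comparisons, file.path(dir, "comparisons.csv"))
  summaries <- list()
  for (model in names(result$fits)) {
    ps <- collect_posteriors(result$fits[[model]])
    for (nm in names(ps)) {
      p <- ps[[nm]]
      utils::write.csv(
        data.frame(draw = seq_along(p$draws), jnd = p$draws),
        file.path(dir, "posteriors",
                  paste0(gsub(":", "_", nm), "_", model, ".csv")),
        row.names = FALSE, quote = FALSE)
      summaries[[model]][[nm]] <- list(
        point_estimate = p$point_estimate, ci95 = unname(p$ci95),
        flat = p$flat, rhat = p$diagnostics$rhat,
        ess = p$diagnostics$ess, n_obs = p$diagnostics$n_obs)
    }
  }
  jsonlite::write_json(
    list(settings = result$settings,
         n_dropped_comparisons = attr(result$comparisons, "n_dropped"),
         posteriors = summaries,
         waic = result$waic_table,
         cohort = unclass(result$cohort),
         normality = result$normality,
         perception = result$perception),
    file.path(dir, "results.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.jnd_pipeline <- function(x, ...) {
  cat("Metabolic-rate perception pipeline\n")
  print(x$cohort)
  cat(sprintf("  KS normality: D = %.3f, p = %.3f\n",
              x$normality$statistic, x$normality$p_value))
  cat("  WAIC ranking:\n")
  tab <- x$waic_table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("    %-12s elpd %9.2f (se %.2f)  delta %.2f\n",
                tab$model[i], tab$elpd_waic[i], tab$se[i], tab$delta_elpd[i]))
  }
  for (i in seq_len(nrow(x$perception))) {
    cat(sprintf("  P(perceive %.1f%% change) = %.3f\n",
                x$perception$delta_percent[i], x$perception$probability[i]))
  }
  invisible(x)
}
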
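# End-to-end orchestration: simulate (or load) sessions, derive kinematics,
# detect saccades, build the per-epoch histogram, run the prediction and
# coupling analyses, and write versioned JSON results with a provenance log.

#' Full single-session analysis
#'
#' @param session A `session_record`.
#' @param params Named list of tunables; defaults follow the reference
#'   analysis constants: speed threshold 0.1 %/frame, 250 ms refractory
#'   window, 5 prediction bins, 10 histogram bins, 100 ms correlogram bins,
#'   correlogram window -0.5..0.8 s.
#' @return List: `kin`, `events`, `histogram`, `table_epoch`,
#'   `table_timepoint`, `correlogram` (NULL if no backward saccades).
#' @export
analyze_session <- function(session, params = list()) {
  p <- utils::modifyList(list(
    threshold = 0.1, refractory_ms = 250, keep_first = FALSE,
    n_prediction_bins = 5L, n_histogram_bins = 10L,
    correlogram_window = c(-0.5, 0.8), correlogram_bin_s = 0.1,
    n_shuffles = 100L, seed = 1L
  ), params)
  kin <- session_kinematics(session)
  pl <- interpolate_missing(session$pupil_traces$left)$values
  pr <- interpolate_missing(session$pupil_traces$right)$values
  # head-centered leftward-positive positions, fraction units
  hl <- 0.5 + kin$eye$head_left / 100
  hr <- 0.5 + kin$eye$head_right / 100
  events <- detect_saccades(hl, hr, eye_rate = session$eye_rate,
                            threshold = p$threshold,
                            refractory_ms = p$refractory_ms,
                            keep_first = p$keep_first)
  hist <- saccade_histogram(events, session$trials,
                            behavior_rate = session$behavior_rate,
                            n_bins = p$n_histogram_bins)
  tab_e <- bin_predictors(session, kin, n_bins = p$n_prediction_bins, per = "epoch")
  tab_t <- bin_predictors(session, kin, n_bins = p$n_prediction_bins, per = "timepoint")
  cg <- tryCatch(
    correlogram(kin$asym_raw_eye, events, session$trials,
                window = p$correlogram_window, bin_s = p$correlogram_bin_s,
                n_shuffles = p$n_shuffles, seed = p$seed,
                eye_rate = session$eye_rate, step = kin$step),
    whiskeye_fit_error = function(e) NULL)
  list(kin = kin, events = events, histogram = hist,
       table_epoch = tab_e, table_timepoint = tab_t, correlogram = cg)
}

#' Run the full pipeline from a configuration
#'
#' Stages: `simulate` (or `ingest` from session directories) ->
#' `kinematics` -> `saccades` -> `predict` -> `couple` -> `report`. Results
#' and a machine-readable provenance log are written under
#' `config$output_dir`. Reruns with the same configuration are
#' byte-identical up to the recorded timestamps.
#'
#' @param config Named list or path to a JSON config file. Fields:
#'   `seed`, `output_dir`, `stages` (subset of the above, default all),
#'   `n_sessions`, `generator` (list of [generator_config()] overrides) or
#'   `session_dirs` (paths for ingest mode), and the tunables of
#'   [analyze_session()].
#' @return Invisibly, the results list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg_path <- config
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  } else cfg_path <- NULL
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  stages <- config$stages %||% c("simulate", "kinematics", "saccades",
                                 "predict", "couple", "report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log <- list(package_version = as.character(utils::packageVersion("whiskeye")),
              seed = seed, stages = stages,
              config_md5 = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path)) else NA,
              durations = list())

  tick <- function(name, expr) {
    st <- Sys.time()
    val <- force(expr)
    log$durations[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    val
  }

  # --- sessions
  sessions <- if ("simulate" %in% stages) {
    tick("simulate", {
      n_sessions <- config$n_sessions %||% 1L
      lapply(seq_len(n_sessions), function(i) {
        gc_args <- utils::modifyList(as.list(config$generator %||% list()),
                                     list(seed = child_seed(seed, i)))
        generate_session(do.call(generator_config, gc_args))
      })
    })
  } else if (!is.null(config$session_dirs)) {
    tick("ingest", lapply(config$session_dirs, function(d)
      list(session = read_session(d), truth = NULL)))
  } else {
    we_error("whiskeye_config_error",
             "stage 'simulate' disabled and no session_dirs given: downstream stages have no input")
  }
  log$n_sessions <- length(sessions)

  params <- utils::modifyList(list(seed = seed), as.list(config$params %||% list()))
  need <- function(st) st %in% stages
  if ((need("saccades") || need("predict") || need("couple")) && !need("kinematics"))
    we_error("whiskeye_config_error",
             "stage 'kinematics' disabled but downstream stages require it")

  analyses <- NULL
  if (need("kinematics")) {
    analyses <- tick("analyze", lapply(sessions, function(s)
      analyze_session(s$session, params)))
    log$n_trials <- sum(vapply(sessions, function(s) length(s$session$trials), 0))
  }

  results <- list(config = config, provenance = NULL)

  if (need("saccades")) {
    results$saccades <- tick("saccades", lapply(seq_along(analyses), function(i) {
      ev <- analyses[[i]]$events
      list(session = sessions[[i]]$session$session_id,
           events = as.data.frame(ev),
           histogram_counts = as.vector(analyses[[i]]$histogram$counts),
           histogram_dim = dim(analyses[[i]]$histogram$counts),
           unassigned = analyses[[i]]$histogram$unassigned)
    }))
  }
  if (need("predict")) {
    roc <- tick("roc", roc_analysis(lapply(analyses, `[[`, "table_epoch"),
                                    n_shuffles = params$n_shuffles %||% 100L,
                                    seed = child_seed(seed, 101L)))
    contrib <- tick("contribution",
                    contribution_analysis(lapply(analyses, `[[`, "table_timepoint"),
                                          n_shuffles = params$n_contrib_shuffles %||% 20L,
                                          seed = child_seed(seed, 102L)))
    results$prediction <- list(
      auc = roc$auc, p_vs_null = roc$p_vs_null,
      p_whisker_vs_eye = roc$p_whisker_vs_eye,
      p_pairwise_bins = roc$p_pairwise_bins,
      fidelity = contrib$fidelity, contribution = contrib$contribution,
      fidelity_tests = contrib$tests)
  }
  if (need("couple")) {
    results$coupling <- tick("couple", lapply(seq_along(analyses), function(i) {
      cg <- analyses[[i]]$correlogram
      if (is.null(cg)) return(list(session = sessions[[i]]$session$session_id,
                                   n_events = 0))
      list(session = sessions[[i]]$session$session_id,
           n_events = cg$n_events, lags = cg$lags,
           real_median = cg$real$median, null_median = cg$null$median,
           bins = cg$bins, estimated_lead = estimate_lead(cg))
    }))
  }

  log$total_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  results$provenance <- log
  if (need("report")) {
    write_results(results[setdiff(names(results), "config")],
                  file.path(out_dir, "results.json"))
    jsonlite::write_json(log, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(results)
}

#' Command-line entry point
#'
#' Minimal argument parser for batch runs:
#' `Rscript -e 'whiskeye::main_cli()' <subcommand> --config cfg.json
#' [--out DIR] [--seed N]` with subcommands `run` (full pipeline),
#' `simulate` (generation + report only).
#'
#' @param args Character vector (defaults to the command line).
#' @return Invisibly, the pipeline results.
#' @export
main_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: <run|simulate> --config FILE [--out DIR] [--seed N]")
  sub <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  config <- if (!is.null(opts$config))
    jsonlite::fromJSON(opts$config, simplifyVector = TRUE) else list()
  if (!is.null(opts$out)) config$output_dir <- opts$out
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (sub == "simulate")
    config$stages <- c("simulate", "kinematics", "saccades", "report")
  else if (sub != "run")
    stop(sprintf("unknown subcommand '%s'", sub))
  run_pipeline(config)
}
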
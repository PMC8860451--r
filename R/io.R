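# ---- session store ----------------------------------------------------------

SCHEMA_VERSION <- "1.0"

#' Write a session to a directory store
#'
#' Serialises a `ramp_session` to a directory: `channels.feather` (continuous
#' channels + time), `events.feather` (name/time long table),
#' `trials.feather` plus a `trials.csv` convenience export, and `meta.json`
#' (schema version, seed, task config, generative parameters). Feather files
#' preserve doubles exactly, so a write/read round trip is bit-identical.
#'
#' @param session A `ramp_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrow::write_feather(session$channels, file.path(path, "channels.feather"))
  ev <- purrr::imap_dfr(session$events, function(t, nm) {
    tibble(name = nm, time = as.numeric(t))
  })
  arrow::write_feather(ev, file.path(path, "events.feather"))
  tr <- session$trials
  tr$outcome <- as.character(tr$outcome)
  arrow::write_feather(tr, file.path(path, "trials.feather"))
  readr::write_csv(tr, file.path(path, "trials.csv"))
  meta <- list(
    schema_version = SCHEMA_VERSION,
    seed = session$seed,
    units = list(time = "seconds", rate = "Hz"),
    config = unclass(session$config),
    params = rapply(unclass(session$params), unclass, how = "replace")
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a session from a directory store
#'
#' @param path Directory written by [write_session()].
#' @return A `ramp_session`.
#' @export
read_session <- function(path) {
  need <- c("channels.feather", "events.feather", "trials.feather", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    abort(sprintf("session store invalid: missing %s",
                  paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  if (!identical(meta$schema_version, SCHEMA_VERSION)) {
    abort(sprintf("schema version %s needs migration (expected %s)",
                  meta$schema_version %||% "<none>", SCHEMA_VERSION))
  }
  ev_tab <- arrow::read_feather(file.path(path, "events.feather"))
  events <- split(ev_tab$time, ev_tab$name)
  # preserve canonical event order
  canon <- c("lampoff", "cue", "licks", "reward", "opto", "artifact")
  events <- events[c(intersect(canon, names(events)),
                     setdiff(names(events), canon))]
  trials <- as_tibble(arrow::read_feather(file.path(path, "trials.feather")))
  trials$outcome <- factor(trials$outcome,
                           levels = c("reaction", "early", "reward",
                                      "iti_lick", "no_lick"))
  cfg <- do.call(task_config, lapply(meta$config, function(v)
    if (is.list(v)) unlist(v) else v))
  p <- meta$params
  p$opto <- if (is.null(p$opto)) NULL else p$opto
  gp <- do.call(generative_params, lapply(p, function(v)
    if (is.list(v) && !is.null(names(v))) lapply(v, identity) else v))
  structure(
    list(channels = as_tibble(arrow::read_feather(file.path(path, "channels.feather"))),
         events = events, trials = trials, config = cfg, params = gp,
         seed = meta$seed),
    class = "ramp_session"
  )
}

#' Export / re-import the trial table as CSV
#'
#' @param trials Trial table.
#' @param path CSV path.
#' @return For `read_trials_csv`, the trial table tibble.
#' @export
write_trials_csv <- function(trials, path) {
  tr <- trials
  tr$outcome <- as.character(tr$outcome)
  readr::write_csv(tr, path)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  tr$outcome <- factor(tr$outcome, levels = c("reaction", "early", "reward",
                                              "iti_lick", "no_lick"))
  tr
}

# ---- pipeline ---------------------------------------------------------------

#' Run the full analysis pipeline on one session
#'
#' Executes the standard stage order — simulate (optional), preprocess,
#' behaviour, encoding model, first-lick decoding, single-trial dynamics,
#' movement-state decoding, optogenetic statistics — collecting each stage's
#' result and a content hash for provenance. Stages can be skipped; a stage
#' failure halts with a stage-tagged error while earlier results are kept in
#' the returned report.
#'
#' @param session A `ramp_session` (or `NULL` to simulate with `gp`/`cfg`).
#' @param gp,cfg Generator inputs when `session` is `NULL`.
#' @param stages Character subset of
#'   `c("preprocess","behavior","encode","decode_time","dynamics",
#'   "decode_state","opto")`.
#' @param seed Seed.
#' @param encode_nests Highest encoding nest fitted.
#' @return List of class `pipeline_report`: per-stage results and `hashes`.
#' @export
run_pipeline <- function(session = NULL, gp = generative_params(),
                         cfg = task_config(),
                         stages = c("preprocess", "behavior", "encode",
                                    "decode_time", "dynamics", "decode_state",
                                    "opto"),
                         seed = 1, encode_nests = 5) {
  report <- list(hashes = list())
  note <- function(name, value) {
    report[[name]] <<- value
    report$hashes[[name]] <<- rlang::hash(value)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            parent = e, data = report)
    })
  }
  if (is.null(session)) {
    session <- run_stage("simulate", simulate_session(gp, cfg, seed = seed))
    note("session_meta", list(n_trials = nrow(session$trials), seed = seed))
  }
  fs <- session$config$sampling_rate
  dff <- ctl <- NULL
  if ("preprocess" %in% stages) {
    run_stage("preprocess", {
      f <- remove_singularities(session$channels$gcamp)
      dff <- compute_dff(f, "moving_average", session$trials, fs = fs)
      ctl <- compute_dff(remove_singularities(session$channels$control),
                         "moving_average", session$trials, fs = fs)
      note("preprocess", list(method = "moving_average",
                              n_replaced = attr(f, "n_replaced")))
    })
  } else {
    dff <- session$channels$gcamp
    ctl <- session$channels$control
  }
  if ("behavior" %in% stages) {
    run_stage("behavior", {
      hz <- hazard_function(timing_histogram(session$trials$first_lick_time))
      note("behavior", list(
        hazard = hz,
        outcomes = table(session$trials$outcome),
        baseline_r = baseline_timing_correlation(dff, session$trials,
                                                 "baseline", fs = fs)
      ))
    })
  }
  if ("encode" %in% stages) {
    run_stage("encode", {
      des <- build_design_matrix(session, dff, nest_level = encode_nests,
                                 control_dff = ctl)
      note("encode", fit_nested_ridge(des, seed = seed)$nests)
    })
  }
  iv <- NULL
  if (any(c("decode_time", "dynamics") %in% stages)) {
    iv <- ramping_intervals(session, dff, out_rate = 100)
  }
  if ("decode_time" %in% stages) {
    run_stage("decode_time", {
      fit <- fit_timelick_decoder(session, dff, ctl, seed = seed)
      ts <- select_thresholds(iv)
      note("decode_time", list(nests = fit$nests,
                               slopes = threshold_slope_analysis(iv, ts)))
    })
  }
  if ("dynamics" %in% stages) {
    run_stage("dynamics", {
      note("dynamics", classify_session(iv, seed = seed))
    })
  }
  if ("decode_state" %in% stages) {
    run_stage("decode_state", {
      series <- build_state_series(session, dff)
      fit <- fit_state_model(series, n_boot = 25, seed = seed)
      note("decode_state", list(r_squared = fitted_hazard(fit)$r_squared,
                                coefficients = fit$coefficients))
    })
  }
  if ("opto" %in% stages && any(session$trials$opto_on)) {
    run_stage("opto", {
      note("opto", opto_comparison(session$trials, n_boot = 1e4,
                                   n_perm = 2000, seed = seed))
    })
  }
  structure(report, class = "pipeline_report")
}
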
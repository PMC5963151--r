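#' Experiment configuration
#'
#' Defaults match the simulation protocol: BCL 800 ms, 10 single-cell
#' cycles, 25 integrated cycles, heart-failure calcium scaling 0.7 (both
#' amplitude and decay time constant), LVAD flow 4 L/min.
#'
#' @param bcl_ms basic cycle length (ms)
#' @param n_cycles_cell single-cell / twitch cycles
#' @param n_cycles_system circulation cycles
#' @param hf_amp_factor,hf_tau_factor heart-failure calcium scaling
#' @param lvad_flow_lpm LVAD set flow (L/min)
#' @param method circulation integrator (`"lsoda"` or `"rk4"`)
#' @param seed seed for synthetic-fixture noise (the physics is
#'   deterministic)
#' @return an `experiment_config` object
#' @export
experiment_config <- function(bcl_ms = 800, n_cycles_cell = 10,
                              n_cycles_system = 25,
                              hf_amp_factor = 0.7, hf_tau_factor = 0.7,
                              lvad_flow_lpm = 4, method = "lsoda",
                              seed = 1L) {
  cfg <- list(bcl_ms = bcl_ms, n_cycles_cell = n_cycles_cell,
              n_cycles_system = n_cycles_system,
              hf_amp_factor = hf_amp_factor,
              hf_tau_factor = hf_tau_factor,
              lvad_flow_lpm = lvad_flow_lpm, method = method,
              seed = as.integer(seed))
  stopifnot(bcl_ms > 0, n_cycles_cell >= 2, n_cycles_system >= 2,
            lvad_flow_lpm >= 0, method %in% c("lsoda", "rk4"))
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @param path JSON file path
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname experiment_config
#' @param cfg an `experiment_config`
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(experiment_config))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown config fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(experiment_config, x)
}

#' Run the full three-condition experiment
#'
#' Calcium generation, myofilament activation, the three circulation
#' scenarios (normal, HF, HF+LVAD), hemodynamic summaries and the two
#' canonical condition comparisons (HF vs normal, HF+LVAD vs HF). When
#' `out_dir` is given, writes per-condition trace CSVs, a Table-style
#' summary CSV, the comparison CSV, a plain-text log and a manifest with
#' content hashes; identical configs yield identical manifests.
#'
#' @param config an [experiment_config()]
#' @param out_dir output directory, or `NULL` to skip writing
#' @return list: `scenarios`, `summaries`, `comparison`, `manifest`
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  base_tp <- transient_params(bcl_ms = config$bcl_ms)
  conditions <- c("normal", "hf", "hf_lvad")
  scenarios <- lapply(conditions, function(cond) {
    run_scenario(cond, n_cycles = config$n_cycles_system,
                 bcl_ms = config$bcl_ms,
                 base_transient = base_tp,
                 hf_amp_factor = config$hf_amp_factor,
                 hf_tau_factor = config$hf_tau_factor,
                 lvad_flow_lpm = config$lvad_flow_lpm,
                 method = config$method)
  })
  names(scenarios) <- conditions
  summaries <- lapply(scenarios, summarize_scenario)
  comparison <- compare_conditions(summaries)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (cond in conditions) {
      f <- file.path(out_dir, paste0("traces_", cond, ".csv"))
      utils::write.csv(round_df(scenarios[[cond]]$traces, 6), f,
                       row.names = FALSE)
      files <- c(files, f)
    }
    f_sum <- file.path(out_dir, "summary.csv")
    write_summary_csv(summaries, f_sum)
    f_cmp <- file.path(out_dir, "comparison.csv")
    utils::write.csv(comparison, f_cmp, row.names = FALSE)
    f_cfg <- file.path(out_dir, "config.json")
    write_config(config, f_cfg)
    f_log <- file.path(out_dir, "run.log")
    writeLines(c(
      sprintf("conditions: %s", paste(conditions, collapse = ", ")),
      sprintf("steady-state EDV deltas: %s",
              paste(vapply(scenarios, function(s)
                sprintf("%s lv %.3g rv %.3g", s$condition,
                        s$steady_metric[["lv"]], s$steady_metric[["rv"]]),
                character(1)), collapse = "; "))), f_log)
    files <- c(files, f_sum, f_cmp, f_cfg, f_log)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA)
  }
  list(scenarios = scenarios, summaries = summaries,
       comparison = comparison, manifest = manifest)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
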
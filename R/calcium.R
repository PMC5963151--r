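#' Calcium transient parameter set
#'
#' Parameters of the analytic bi-exponential intracellular calcium transient
#' used to drive the myofilament model. The defaults describe a normal human
#' ventricular transient at a basic cycle length (BCL) of 800 ms: diastolic
#' level 0.1 uM, peak 1.0 uM (amplitude 0.9 uM above diastolic), 20 ms rise
#' and 150 ms decay time constants.
#'
#' @param ca_dia diastolic calcium (uM), > 0
#' @param ca_amp peak amplitude above diastolic (uM), >= 0
#' @param tau_rise rise time constant (ms), > 0
#' @param tau_decay decay time constant (ms), must exceed `tau_rise`
#' @param bcl_ms basic cycle length (ms), > 0
#' @return an object of class `transient_params`
#' @export
transient_params <- function(ca_dia = 0.1, ca_amp = 0.9,
                             tau_rise = 20, tau_decay = 150,
                             bcl_ms = 800) {
  if (!is.numeric(ca_dia) || length(ca_dia) != 1L || !is.finite(ca_dia) ||
      ca_dia <= 0)
    stop("`ca_dia` must be a single positive number", call. = FALSE)
  if (!is.numeric(ca_amp) || length(ca_amp) != 1L || !is.finite(ca_amp) ||
      ca_amp < 0)
    stop("`ca_amp` must be a single non-negative number", call. = FALSE)
  for (nm in c("tau_rise", "tau_decay", "bcl_ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm),
           call. = FALSE)
  }
  if (tau_rise >= tau_decay)
    stop("`tau_rise` must be strictly less than `tau_decay`", call. = FALSE)
  structure(list(ca_dia = ca_dia, ca_amp = ca_amp, tau_rise = tau_rise,
                 tau_decay = tau_decay, bcl_ms = bcl_ms),
            class = "transient_params")
}

#' @export
print.transient_params <- function(x, ...) {
  cat("Calcium transient parameters\n")
  cat(sprintf("  diastolic %.3g uM, amplitude %.3g uM (peak %.3g uM)\n",
              x$ca_dia, x$ca_amp, x$ca_dia + x$ca_amp))
  cat(sprintf("  tau_rise %.3g ms, tau_decay %.3g ms, BCL %g ms\n",
              x$tau_rise, x$tau_decay, x$bcl_ms))
  invisible(x)
}

# time of the bi-exponential maximum, closed form
biexp_peak_time <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

#' Generate one beat of an analytic calcium transient
#'
#' Evaluates Ca(t) = ca_dia + ca_amp * (exp(-t/tau_decay) - exp(-t/tau_rise))
#' / M on a regular grid over one cycle, where M is the maximum of the
#' bi-exponential so that the peak equals `ca_dia + ca_amp` exactly.
#'
#' @param params a [transient_params()] object
#' @param dt sampling step (ms); must satisfy `dt <= bcl_ms / 100`
#' @return a `calcium_transient` with fields `time_ms`, `ca_uM`, `bcl_ms`,
#'   `diastolic_uM`
#' @export
make_transient <- function(params, dt = 1) {
  stopifnot(inherits(params, "transient_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  if (dt > params$bcl_ms / 100)
    stop("`dt` must not exceed bcl_ms/100", call. = FALSE)
  t <- seq(0, params$bcl_ms - dt, by = dt)
  if (params$ca_amp == 0) {
    ca <- rep(params$ca_dia, length(t))
  } else {
    # include the closed-form peak time so the sampled maximum equals
    # ca_dia + ca_amp exactly
    tstar <- biexp_peak_time(params$tau_rise, params$tau_decay)
    t <- sort(unique(c(t, tstar)))
    m <- exp(-tstar / params$tau_decay) - exp(-tstar / params$tau_rise)
    shape <- (exp(-t / params$tau_decay) - exp(-t / params$tau_rise)) / m
    ca <- params$ca_dia + params$ca_amp * shape
  }
  new_calcium_transient(t, ca, params$bcl_ms, params$ca_dia)
}

new_calcium_transient <- function(time_ms, ca_uM, bcl_ms, diastolic_uM) {
  stopifnot(length(time_ms) == length(ca_uM),
            all(diff(time_ms) > 0),
            time_ms[1] >= 0, time_ms[length(time_ms)] < bcl_ms)
  structure(list(time_ms = time_ms, ca_uM = ca_uM, bcl_ms = bcl_ms,
                 diastolic_uM = diastolic_uM),
            class = "calcium_transient")
}

#' @export
print.calcium_transient <- function(x, ...) {
  cat(sprintf(paste0("Calcium transient: %d samples over BCL %g ms, ",
                     "diastolic %.3g, peak %.3g\n"),
              length(x$time_ms), x$bcl_ms, x$diastolic_uM, max(x$ca_uM)))
  invisible(x)
}

#' Apply heart-failure remodeling to transient parameters
#'
#' Systolic dysfunction is induced by scaling the transient magnitude
#' (peak above diastolic) and the decay time constant. The defaults scale
#' both to 70% of normal. Diastolic calcium and rise kinetics are unchanged.
#'
#' @param params a [transient_params()] object
#' @param amp_factor amplitude scaling in (0, 1]; default 0.7
#' @param tau_factor decay-time-constant scaling in (0, 1]; default 0.7
#' @return remodeled `transient_params`
#' @export
apply_hf_remodeling <- function(params, amp_factor = 0.7, tau_factor = 0.7) {
  stopifnot(inherits(params, "transient_params"))
  for (nm in c("amp_factor", "tau_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0 || v > 1)
      stop(sprintf("`%s` must lie in (0, 1]", nm), call. = FALSE)
  }
  transient_params(ca_dia = params$ca_dia,
                   ca_amp = params$ca_amp * amp_factor,
                   tau_rise = params$tau_rise,
                   tau_decay = params$tau_decay * tau_factor,
                   bcl_ms = params$bcl_ms)
}

#' Normalize a calcium transient by a reference peak
#'
#' Divides the calcium values by `reference_peak`, yielding a dimensionless
#' trace. Normalizing the normal-condition transient by its own peak gives a
#' maximum of exactly 1; the heart-failure transient normalized by the normal
#' peak then shows its relative magnitude directly.
#'
#' @param ct a `calcium_transient`
#' @param reference_peak positive reference (uM)
#' @return a `calcium_transient` with dimensionless values
#' @export
normalize_to_reference <- function(ct, reference_peak) {
  stopifnot(inherits(ct, "calcium_transient"))
  if (!is.numeric(reference_peak) || length(reference_peak) != 1L ||
      !is.finite(reference_peak) || reference_peak <= 0)
    stop("`reference_peak` must be a single positive number", call. = FALSE)
  new_calcium_transient(ct$time_ms, ct$ca_uM / reference_peak, ct$bcl_ms,
                        ct$diastolic_uM / reference_peak)
}

#' Sample a periodic calcium transient at an absolute time
#'
#' Returns Ca at `t_ms mod bcl_ms` by linear interpolation on the beat grid,
#' wrapping between the last grid node and the first node of the next beat.
#'
#' @param ct a `calcium_transient`
#' @param t_ms absolute time(s) in ms, >= 0 (vectorized)
#' @return calcium value(s) (uM)
#' @export
sample_periodic <- function(ct, t_ms) {
  stopifnot(inherits(ct, "calcium_transient"))
  if (any(t_ms < 0)) stop("`t_ms` must be >= 0", call. = FALSE)
  tt <- t_ms %% ct$bcl_ms
  # append the wrap point (start of next beat) so the final interval of the
  # cycle interpolates toward the beat-onset value
  tg <- c(ct$time_ms, ct$bcl_ms)
  cg <- c(ct$ca_uM, ct$ca_uM[1])
  stats::approx(tg, cg, xout = tt, rule = 2)$y
}

#' Write / read a calcium transient as CSV with a JSON sidecar
#'
#' The CSV holds two columns (`time_ms`, `ca_uM`); the sidecar
#' (`<path>.json`) carries `bcl_ms` and `diastolic_uM`.
#'
#' @param ct a `calcium_transient`
#' @param path CSV file path
#' @return `path`, invisibly
#' @export
write_transient_csv <- function(ct, path) {
  stopifnot(inherits(ct, "calcium_transient"))
  utils::write.csv(data.frame(time_ms = ct$time_ms, ca_uM = ct$ca_uM),
                   path, row.names = FALSE)
  jsonlite::write_json(list(bcl_ms = ct$bcl_ms,
                            diastolic_uM = ct$diastolic_uM),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transient_csv
#' @export
read_transient_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_calcium_transient(df$time_ms, df$ca_uM, meta$bcl_ms, meta$diastolic_uM)
}
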
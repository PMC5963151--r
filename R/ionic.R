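#' Resting initial state of the human ventricular ionic model
#'
#' Returns the published resting initial conditions of the human ventricular
#' membrane-kinetics formulation used throughout the package (epicardial by
#' default). The state holds membrane potential (mV), twelve gating
#' variables in \[0,1\], and intracellular Ca, SR Ca, Na and K (mM).
#'
#' @param cell_type one of `"epi"`, `"endo"`, `"mid"`
#' @return a named numeric vector of class `membrane_state`
#' @export
init_state <- function(cell_type = c("epi", "endo", "mid")) {
  cell_type <- match.arg(cell_type)
  s <- tnnp_init_cpp()
  attr(s, "cell_type") <- cell_type
  class(s) <- "membrane_state"
  s
}

#' @export
print.membrane_state <- function(x, ...) {
  cat(sprintf("Membrane state (%s cell): V = %.2f mV, Cai = %.4g mM\n",
              attr(x, "cell_type"), x[["v_m"]], x[["ca_i"]]))
  invisible(x)
}

gate_names <- function() c("m", "h", "j", "xr1", "xr2", "xs", "r", "s",
                           "d", "f", "f_ca", "g")

#' Transmembrane ionic current breakdown
#'
#' Evaluates the twelve membrane currents of the formulation at the given
#' state; `i_ion` is their exact sum (pA/pF).
#'
#' @param state a `membrane_state`
#' @return named numeric vector of class `current_breakdown`
#' @export
compute_currents <- function(state) {
  stopifnot(inherits(state, "membrane_state"))
  out <- tnnp_currents_cpp(as.numeric(state), attr(state, "cell_type"))
  class(out) <- "current_breakdown"
  out
}

#' @export
print.current_breakdown <- function(x, ...) {
  y <- unclass(x)
  cat("Ionic currents (pA/pF):\n")
  print(round(y, 5))
  invisible(x)
}

#' Advance the ionic model one time step
#'
#' Forward-Euler update of all state variables (optionally Rush-Larsen for
#' the gates). The stimulus follows the inward-negative convention: a
#' depolarizing stimulus is negative (default pacing uses -52 pA/pF for
#' 1 ms), and dV/dt = -(i_ion + i_stim).
#'
#' @param state a `membrane_state`
#' @param dt time step (ms); at most 0.02 for forward Euler, 0.1 with
#'   Rush-Larsen gate updates
#' @param i_stim stimulus current density (pA/pF), inward negative
#' @param rush_larsen use exponential (Rush-Larsen) gate updates
#' @return the advanced `membrane_state`
#' @export
step_state <- function(state, dt = 0.01, i_stim = 0, rush_larsen = FALSE) {
  stopifnot(inherits(state, "membrane_state"))
  lim <- if (rush_larsen) 0.1 else 0.02
  if (!is.finite(dt) || dt <= 0 || dt > lim)
    stop(sprintf("dt must be in (0, %g] ms", lim), call. = FALSE)
  out <- tnnp_step_cpp(as.numeric(state), dt, i_stim,
                       attr(state, "cell_type"), rush_larsen)
  attributes(out) <- attributes(state)
  names(out) <- names(state)
  out
}

#' Pace a single cell to steady state
#'
#' Applies a fixed-cycle-length stimulus train and records membrane
#' potential and intracellular calcium. The steady-state metric is the
#' relative change in calcium-transient peak between the last two beats.
#'
#' @param cell_type `"epi"`, `"endo"` or `"mid"`
#' @param bcl_ms basic cycle length (ms), default 800
#' @param n_beats number of paced beats, >= 2, default 10
#' @param stim_amp stimulus amplitude (pA/pF, inward negative), default -52
#' @param stim_dur stimulus duration (ms), default 1
#' @param dt integration step (ms), default 0.01
#' @param record_dt recording interval (ms), default 1
#' @param rush_larsen use Rush-Larsen gate updates
#' @return a `pacing_result` list: `time_ms`, `v_m`, `ca_i_mM`, `bcl_ms`,
#'   `n_beats`, `steady_metric`, `final_state`
#' @export
pace_to_steady_state <- function(cell_type = "epi", bcl_ms = 800,
                                 n_beats = 10, stim_amp = -52,
                                 stim_dur = 1, dt = 0.01, record_dt = 1,
                                 rush_larsen = FALSE) {
  if (n_beats < 2) stop("n_beats must be >= 2", call. = FALSE)
  res <- tnnp_pace_cpp(cell_type, bcl_ms, as.integer(n_beats), dt,
                       stim_amp, stim_dur, record_dt, rush_larsen,
                       numeric(0))
  out <- list(time_ms = res$time_ms, v_m = res$v_m, ca_i_mM = res$ca_i_mM,
              bcl_ms = bcl_ms, n_beats = n_beats,
              cell_type = cell_type, final_state = res$final_state)
  pk <- beat_ca_peaks(out)
  out$steady_metric <- abs(pk[n_beats] - pk[n_beats - 1]) / pk[n_beats]
  class(out) <- "pacing_result"
  out
}

#' @export
print.pacing_result <- function(x, ...) {
  cat(sprintf(paste0("Pacing result: %d beats at BCL %g ms (%s cell), ",
                     "steady-state metric %.3g\n"),
              x$n_beats, x$bcl_ms, x$cell_type, x$steady_metric))
  invisible(x)
}

beat_rows <- function(traces, i) {
  t0 <- (i - 1) * traces$bcl_ms
  t1 <- i * traces$bcl_ms
  which(traces$time_ms >= t0 - 1e-9 & traces$time_ms < t1 - 1e-9)
}

beat_ca_peaks <- function(traces) {
  vapply(seq_len(traces$n_beats),
         function(i) max(traces$ca_i_mM[beat_rows(traces, i)]),
         numeric(1))
}

#' Extract one beat's calcium transient from a pacing run
#'
#' Converts the chosen beat's intracellular calcium (mM) to a
#' `calcium_transient` in uM on a beat-local time grid.
#'
#' @param traces a `pacing_result`
#' @param beat_index beat number, or `"last"` (default)
#' @return a `calcium_transient`
#' @export
extract_calcium_transient <- function(traces, beat_index = "last") {
  stopifnot(inherits(traces, "pacing_result"))
  i <- if (identical(beat_index, "last")) traces$n_beats
       else as.integer(beat_index)
  if (i < 1 || i > traces$n_beats)
    stop("beat index out of range", call. = FALSE)
  idx <- beat_rows(traces, i)
  t <- traces$time_ms[idx] - (i - 1) * traces$bcl_ms
  ca <- traces$ca_i_mM[idx] * 1000
  new_calcium_transient(t, ca, traces$bcl_ms, ca[1])
}
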
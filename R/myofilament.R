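#' Relaxed cross-bridge state
#'
#' All regulatory units nonpermissive, no attached cross-bridges, troponin
#' equilibrated at diastolic calcium, distortions at their unloaded values.
#'
#' @param sl initial sarcomere length (um), within \[1.4, 2.4\]
#' @param ca_dia diastolic calcium (uM) used to equilibrate troponin
#' @return a named numeric vector of class `xb_state`
#' @export
init_xb_state <- function(sl = 2.2, ca_dia = 0.1) {
  s <- xb_init_cpp(sl, ca_dia)
  class(s) <- "xb_state"
  s
}

#' @export
print.xb_state <- function(x, ...) {
  cat(sprintf(
    "Cross-bridge state: N %.3f P %.3f preR %.4f postR %.4f, SL %.3f um\n",
    x[["n_xb"]], x[["p_xb"]], x[["xb_prer"]], x[["xb_postr"]], x[["sl"]]))
  cat(sprintf("  active tension %.3f kPa\n", active_tension(x)))
  invisible(x)
}

#' Advance the cross-bridge model one step
#'
#' Explicit update of regulatory-unit fractions, attached-state fractions,
#' mean distortions, troponin calcium binding, and (in isotonic mode)
#' sarcomere length toward the force balance active + passive = load.
#'
#' @param state an `xb_state`
#' @param ca_uM calcium concentration (uM), >= 0
#' @param dt time step (ms), <= 0.1
#' @param mode `"isometric"` (length clamp) or `"isotonic"`
#' @param load_kpa applied load (kPa), used in isotonic mode
#' @return the advanced `xb_state`
#' @export
step_xb <- function(state, ca_uM, dt = 0.01,
                    mode = c("isometric", "isotonic"), load_kpa = 10) {
  stopifnot(inherits(state, "xb_state"))
  mode <- match.arg(mode)
  out <- xb_step_cpp(as.numeric(state), ca_uM, dt,
                     if (mode == "isotonic") 1L else 0L, load_kpa)
  class(out) <- "xb_state"
  out
}

#' Active tension of a cross-bridge state
#'
#' Tension is proportional to the attached fractions weighted by their mean
#' distortions and the thick-filament overlap fraction; a fully relaxed
#' state produces zero.
#'
#' @param state an `xb_state`
#' @return active tension (kPa)
#' @export
active_tension <- function(state) {
  xb_tension_cpp(as.numeric(state))
}

#' Passive (titin + collagen) tension at a sarcomere length
#'
#' @param sl sarcomere length (um)
#' @return passive tension (kPa); negative below slack length
#' @export
passive_tension <- function(sl) {
  vapply(sl, xb_passive_cpp, numeric(1))
}

#' Run a periodic twitch protocol
#'
#' Drives the cross-bridge model with a periodic calcium transient for
#' `n_beats` cycles and returns the last beat (steady cycling). The
#' isometric protocol can be realized either as a hard length clamp or as
#' the very-high-load isotonic limit (load = 1000 kPa); both give the same
#' tension because at that load the sarcomere settles on the stiff collagen
#' segment and barely moves during the twitch.
#'
#' @param ct a `calcium_transient`
#' @param mode `"isometric"` or `"isotonic"`
#' @param load_kpa applied load (kPa): 10 for the standard isotonic
#'   protocol, 1000 for the high-load isometric realization
#' @param sl0 initial sarcomere length (um)
#' @param n_beats number of cycles (default 10); the last is returned
#' @param dt integration step (ms)
#' @param record_dt recording interval (ms)
#' @param isometric_as `"clamp"` (default) or `"high_load"`
#' @return a `twitch_result`: `time_ms`, `tension_kpa`, `sl_um`,
#'   `sl_norm` (normalized by the beat-onset length), `atp_rate`,
#'   `frac_sum`, plus `mode`, `load_kpa`, `peak_shortening_by_beat`
#' @export
run_twitch <- function(ct, mode = c("isometric", "isotonic"),
                       load_kpa = NULL, sl0 = 2.2, n_beats = 10,
                       dt = 0.01, record_dt = 1,
                       isometric_as = c("clamp", "high_load")) {
  stopifnot(inherits(ct, "calcium_transient"))
  mode <- match.arg(mode)
  isometric_as <- match.arg(isometric_as)
  if (is.null(load_kpa)) load_kpa <- if (mode == "isometric") 1000 else 10
  if (load_kpa <= 0) stop("load_kpa must be > 0", call. = FALSE)
  cpp_mode <- if (mode == "isotonic" ||
                  (mode == "isometric" && isometric_as == "high_load"))
    1L else 0L
  n_steps <- round(n_beats * ct$bcl_ms / dt)
  ca <- sample_periodic(ct, (seq_len(n_steps) - 1) * dt)
  s0 <- init_xb_state(sl0, ca_dia = min(ct$ca_uM))
  rec_every <- max(1L, round(record_dt / dt))
  res <- xb_run_cpp(as.numeric(s0), ca, dt, cpp_mode, load_kpa, rec_every)
  t <- res$time_ms
  # per-beat peak shortening for steady-cycling diagnostics
  beat_of <- pmin(floor(t / ct$bcl_ms) + 1, n_beats)
  short_by_beat <- tapply(res$sl_um, beat_of, min)
  last <- beat_of == n_beats
  t_loc <- t[last] - (n_beats - 1) * ct$bcl_ms
  sl <- res$sl_um[last]
  structure(list(time_ms = t_loc,
                 tension_kpa = res$tension_kpa[last],
                 sl_um = sl,
                 sl_norm = sl / sl[1],
                 atp_rate = res$atp_rate[last],
                 frac_sum = res$frac_sum[last],
                 mode = mode, load_kpa = load_kpa, bcl_ms = ct$bcl_ms,
                 peak_shortening_by_beat = as.numeric(short_by_beat),
                 final_state = structure(res$final_state,
                                         class = "xb_state")),
            class = "twitch_result")
}

#' @export
print.twitch_result <- function(x, ...) {
  cat(sprintf(
    "Twitch (%s, load %g kPa): peak tension %.2f kPa, min SL %.3f um\n",
    x$mode, x$load_kpa, max(x$tension_kpa), min(x$sl_um)))
  invisible(x)
}

#' Normalized ATP consumption rate of a twitch
#'
#' The ATP consumption rate is the post-rotation detachment flux (each
#' detachment hydrolyzes one ATP) scaled by filament overlap; it is reported
#' normalized by a reference peak, conventionally the peak rate of the
#' normal isometric twitch.
#'
#' @param result a `twitch_result`
#' @param normalizing_peak positive reference peak rate
#' @return numeric trace of normalized ATP rate
#' @export
atp_consumption <- function(result, normalizing_peak) {
  stopifnot(inherits(result, "twitch_result"))
  if (!is.finite(normalizing_peak) || normalizing_peak <= 0)
    stop("`normalizing_peak` must be > 0", call. = FALSE)
  result$atp_rate / normalizing_peak
}

#' Steady-state force-calcium relation (algebraic)
#'
#' Solves the regulatory/cross-bridge rate balance algebraically at each
#' fixed calcium level and fixed sarcomere length: troponin saturations,
#' permissiveness, then the linear steady state of the four-state cycle
#' with distortions at their isometric fixed point. Serves as the
#' independent reference surface for the time-marched model.
#'
#' @param sl sarcomere length (um)
#' @param ca_grid increasing positive calcium levels (uM)
#' @return data frame: ca_uM, tension_kpa (sigmoidal, nondecreasing)
#' @export
steady_state_force_ca <- function(sl = 2.2, ca_grid = 10^seq(-1.5, 1, 0.1)) {
  if (any(ca_grid <= 0) || is.unsorted(ca_grid))
    stop("ca_grid must be positive and increasing", call. = FALSE)
  p <- as.list(xb_params_cpp())
  ze <- min(p$len_thick / 2, sl / 2)
  cle <- max(sl / 2 - (sl - p$len_thin), p$len_hbare / 2)
  sovt <- max(0, ze - cle) * 2 / (p$len_thick - p$len_hbare)
  sovn <- max(0, ze - cle) / p$len_thin
  tension <- vapply(ca_grid, function(ca) {
    L <- p$kon * ca / (p$kon * ca + p$koffL)
    H <- p$kon * ca / (p$kon * ca + p$koffH)
    treg <- (1 - sovn) * L + sovn * H
    permtot <- sqrt(1 / (1 + (p$perm50 / max(treg, 1e-12))^p$nperm))
    knp <- p$kn_p * permtot
    kpn <- p$kp_n * min(100, 1 / permtot)
    gappT <- p$gapp * (1 + (1 - sovt) * p$gslmod)
    # isometric distortion fixed point: x_prer = 0, x_postr = x_0, so the
    # strain-modulated rates reduce to their reference values
    pre <- 1
    post <- p$hf * pre / (p$hb + p$gxb)
    P <- ((gappT + p$hf) * pre - p$hb * post) / p$fapp
    N <- if (knp > 0) kpn * P / knp else Inf
    tot <- N + P + pre + post
    p$kxb * sovt * (post / tot)
  }, numeric(1))
  data.frame(ca_uM = ca_grid, tension_kpa = tension)
}
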
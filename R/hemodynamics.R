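#' Extract the last full beat from multi-beat traces
#'
#' Returns the final full window of one basic cycle length, aligned to beat
#' onset (integer multiples of `bcl_ms` from the start of the trace, i.e. the
#' activation onset used by the pacing protocol).
#'
#' @param traces data frame with a `time_ms` column plus signal columns
#' @param bcl_ms basic cycle length (ms)
#' @return data frame slice spanning exactly one cycle
#' @export
segment_last_beat <- function(traces, bcl_ms) {
  stopifnot(is.data.frame(traces), "time_ms" %in% names(traces))
  t <- traces$time_ms
  span <- t[length(t)] - t[1]
  if (span < bcl_ms - 1e-9)
    stop("traces must span at least one full cycle", call. = FALSE)
  n_full <- floor((span + 1e-9) / bcl_ms)
  t0 <- t[1] + (n_full - 1) * bcl_ms
  t1 <- t0 + bcl_ms
  out <- traces[t >= t0 - 1e-9 & t <= t1 + 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize one beat of ventricular pressure-volume traces
#'
#' Computes the standard PV-loop indices per ventricle: end-diastolic volume
#' (EDV, max volume), end-systolic volume (ESV, min volume), end-diastolic
#' pressure (EDP, ventricular pressure at the EDV sample), end-systolic
#' pressure (ESP, peak ventricular pressure by default, or pressure at the
#' ESV sample with `esp_mode = "at_esv"`), pulse pressure PP = ESP - EDP,
#' stroke volume SV = EDV - ESV, ejection fraction EF = 100*SV/EDV, cardiac
#' output CO = SV * (60000/bcl_ms) / 1000 (L/min), and stroke work SW =
#' |loop area| by the shoelace rule. Right-atrial and pulmonary-arterial
#' end-systolic pressures are the maxima of their traces when present.
#' Negative EDP (below atmospheric) is legal and preserved.
#'
#' @param beat one-beat data frame with columns `time_ms`, `p_lv`, `v_lv`
#'   and optionally `p_rv`, `v_rv`, `p_ra`, `p_pa`
#' @param bcl_ms basic cycle length (ms)
#' @param esp_mode `"peak"` (default) or `"at_esv"`
#' @return a `hemo_summary` list with elements `lv`, `rv` (each esp, edp,
#'   pp, edv, esv, sv, ef, co, sw), `raesp`, `paesp`, `bcl_ms`
#' @export
summarize_beat <- function(beat, bcl_ms, esp_mode = c("peak", "at_esv")) {
  esp_mode <- match.arg(esp_mode)
  stopifnot(is.data.frame(beat), all(c("p_lv", "v_lv") %in% names(beat)))
  one <- function(p, v) {
    edv <- max(v); esv <- min(v)
    # end-diastole = first arrival on the EDV plateau, robust to
    # sub-microliter drift during the isovolumetric phase
    tol <- max(1e-6 * (edv - esv), 1e-9)
    edp <- p[which(v >= edv - tol)[1]]
    esp <- if (esp_mode == "peak") max(p) else p[which(v <= esv + tol)[1]]
    sv <- edv - esv
    list(esp = esp, edp = edp, pp = esp - edp,
         edv = edv, esv = esv, sv = sv,
         ef = 100 * sv / edv,
         co = sv * (60000 / bcl_ms) / 1000,
         sw = loop_area(p, v, sv))
  }
  out <- list(lv = one(beat$p_lv, beat$v_lv))
  out$rv <- if (all(c("p_rv", "v_rv") %in% names(beat)))
    one(beat$p_rv, beat$v_rv) else NULL
  out$raesp <- if ("p_ra" %in% names(beat)) max(beat$p_ra) else NA_real_
  out$paesp <- if ("p_pa" %in% names(beat)) max(beat$p_pa) else NA_real_
  out$bcl_ms <- bcl_ms
  class(out) <- "hemo_summary"
  out
}

# shoelace area of the PV loop; closes the loop by appending the first
# point, warning when the endpoint volume gap exceeds 1% of SV
loop_area <- function(p, v, sv) {
  n <- length(v)
  if (sv > 0 && abs(v[n] - v[1]) > 0.01 * sv)
    warning("PV loop not closed; closing by appending the first point",
            call. = FALSE)
  p2 <- c(p, p[1]); v2 <- c(v, v[1])
  abs(sum(p2[-length(p2)] * diff(v2) + diff(p2) * diff(v2) / 2))
}

#' @export
print.hemo_summary <- function(x, ...) {
  fmt <- function(s, lab) {
    cat(sprintf(
      "  %s: ESP %.1f EDP %.1f PP %.1f mmHg | EDV %.1f ESV %.1f SV %.1f mL | EF %.1f%% CO %.2f L/min SW %.0f mmHg*mL\n",
      lab, s$esp, s$edp, s$pp, s$edv, s$esv, s$sv, s$ef, s$co, s$sw))
  }
  cat(sprintf("Hemodynamic summary (BCL %g ms)\n", x$bcl_ms))
  fmt(x$lv, "LV")
  if (!is.null(x$rv)) fmt(x$rv, "RV")
  if (is.finite(x$raesp) || is.finite(x$paesp))
    cat(sprintf("  RAESP %.1f mmHg, PAESP %.1f mmHg\n", x$raesp, x$paesp))
  invisible(x)
}

#' Signed percent change
#'
#' @param baseline baseline value, nonzero
#' @param new new value
#' @return 100 * (new - baseline) / baseline
#' @export
percent_change <- function(baseline, new) {
  if (any(baseline == 0))
    stop("percent change undefined for zero baseline", call. = FALSE)
  100 * (new - baseline) / baseline
}

#' Tabulate condition-vs-condition changes of hemodynamic quantities
#'
#' @param summaries named list of `hemo_summary` objects (or flat named
#'   numeric vectors of quantities), one per condition
#' @param pairs list of c(baseline, new) condition-name pairs; default
#'   compares heart failure to normal and LVAD-treated to heart failure
#' @return data frame with columns quantity, baseline_condition,
#'   new_condition, baseline, new, pct_change
#' @export
compare_conditions <- function(summaries,
                               pairs = list(c("normal", "hf"),
                                            c("hf", "hf_lvad"))) {
  flat <- lapply(summaries, flatten_summary)
  rows <- list()
  for (pr in pairs) {
    if (!all(pr %in% names(flat)))
      stop(sprintf("unknown condition in pair (%s, %s)", pr[1], pr[2]),
           call. = FALSE)
    a <- flat[[pr[1]]]; b <- flat[[pr[2]]]
    qs <- intersect(names(a), names(b))
    qs <- qs[is.finite(a[qs]) & is.finite(b[qs]) & a[qs] != 0]
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = qs,
      baseline_condition = pr[1], new_condition = pr[2],
      baseline = unname(a[qs]), new = unname(b[qs]),
      pct_change = unname(percent_change(a[qs], b[qs])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

flatten_summary <- function(s) {
  if (is.numeric(s)) return(s)
  stopifnot(inherits(s, "hemo_summary"))
  v <- c(unlist(lapply(s$lv, identity)))
  names(v) <- paste0("lv", names(s$lv))
  if (!is.null(s$rv)) {
    r <- unlist(s$rv); names(r) <- paste0("rv", names(s$rv))
    v <- c(v, r)
  }
  c(v, raesp = s$raesp, paesp = s$paesp)
}

#' Detect isovolumetric phases in a beat
#'
#' Intervals where ventricular volume is constant — instantaneous drift
#' below a third of `dv_thresh` per 10 ms and total excursion inside the
#' `dv_thresh` band — sustained for at least `min_ms`, while pressure
#' changes by more than `dp_min` over the interval. A continuous-flow LVAD
#' drains the ventricle throughout systole and so abolishes these phases in
#' the left ventricle.
#'
#' @param beat one-beat data frame with `time_ms` and the chosen ventricle's
#'   pressure/volume columns
#' @param dv_thresh volume-constancy band (mL), > 0
#' @param min_ms minimum sustained duration (ms)
#' @param dp_min minimum pressure excursion (mmHg) for an interval to count
#' @param ventricle `"lv"` or `"rv"`
#' @return data frame with columns start_ms, end_ms (possibly zero rows)
#' @export
isovolumetric_phases <- function(beat, dv_thresh = 1, min_ms = 20,
                                 dp_min = 5, ventricle = c("lv", "rv")) {
  ventricle <- match.arg(ventricle)
  stopifnot(dv_thresh > 0)
  p <- beat[[paste0("p_", ventricle)]]
  v <- beat[[paste0("v_", ventricle)]]
  t <- beat$time_ms
  dvdt <- c(diff(v) / diff(t), 0) * 10           # mL per 10 ms
  # candidate samples: instantaneous drift well inside the constancy band
  # (a continuous-flow pump drains at ~2/3 of the default band per 10 ms
  # and must not register as isovolumetric)
  flat <- abs(dvdt) < dv_thresh / 3
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (t[i1] - t[i0] < min_ms) next
    if (diff(range(p[i0:i1])) <= dp_min) next
    # and the volume must stay inside the constancy band over the whole
    # interval, not merely drift slowly
    if (diff(range(v[i0:i1])) >= dv_thresh) next
    out <- rbind(out, data.frame(start_ms = t[i0], end_ms = t[i1]))
  }
  out
}

#' Synthetic pressure-volume beat fixture
#'
#' Builds a smooth four-phase PV loop (filling, isovolumetric contraction,
#' ejection, isovolumetric relaxation) that hits prescribed end-systolic /
#' end-diastolic pressures and volumes exactly, for exercising the
#' summarizer without running the circulation model. Time starts at end
#' systole (minimum volume) so the final sample returns there and the loop
#' closes. Optional seeded Gaussian noise perturbs interior samples only, so
#' the prescribed extremes are preserved.
#'
#' @param esp,edp prescribed end-systolic / end-diastolic pressures (mmHg);
#'   `edp` may be negative
#' @param edv,esv prescribed end-diastolic / end-systolic volumes (mL),
#'   `edv > esv`
#' @param bcl_ms cycle length (ms)
#' @param n number of samples
#' @param noise_sd standard deviation of optional pressure/volume noise
#' @param seed RNG seed used when `noise_sd > 0`
#' @return data frame with columns `time_ms`, `p_lv`, `v_lv`
#' @export
synth_pv_fixture <- function(esp, edp, edv, esv, bcl_ms = 800, n = 400,
                             noise_sd = 0, seed = 1L) {
  if (edv <= esv) stop("`edv` must exceed `esv`", call. = FALSE)
  ph <- c(0.40, 0.10, 0.35, 0.15)  # fill, ivc, eject, ivr fractions
  nseg <- pmax(3L, round(ph * n))
  smooth01 <- function(m) (1 - cos(seq(0, pi, length.out = m))) / 2
  # phase 1: filling at ESV..EDV along a low-pressure limb ending at EDP
  s1 <- smooth01(nseg[1])
  v1 <- esv + (edv - esv) * s1
  p_fill_lo <- edp - 1 - 0.5 * abs(edp)  # filling limb starts below EDP
  p1 <- p_fill_lo + (edp - p_fill_lo) * s1^2
  # phase 2: isovolumetric contraction at EDV, EDP -> ESP
  s2 <- smooth01(nseg[2])
  v2 <- rep(edv, nseg[2])
  p2 <- edp + (esp - edp) * s2
  # phase 3: ejection EDV -> ESV near ESP (slight rounded dome, peak = ESP)
  s3 <- smooth01(nseg[3])
  v3 <- edv - (edv - esv) * s3
  p3 <- esp - (esp - edp) * 0.15 * s3^2 * (1 - sin(pi * s3) * 0.3)
  p3[1] <- esp
  # phase 4: isovolumetric relaxation at ESV, back down to the loop start
  s4 <- smooth01(nseg[4])
  v4 <- rep(esv, nseg[4])
  p_start <- p_fill_lo
  p4 <- p3[length(p3)] + (p_start - p3[length(p3)]) * s4
  p <- c(p1, p2, p3, p4)
  v <- c(v1, v2, v3, v4)
  if (noise_sd > 0) {
    set.seed(seed)
    idx <- seq_along(p)
    protect <- c(which.max(v), which.min(v), which.max(p), which.min(p))
    pick <- setdiff(idx, protect)
    p[pick] <- p[pick] + stats::rnorm(length(pick), 0, noise_sd)
    v[pick] <- v[pick] + stats::rnorm(length(pick), 0, noise_sd) * 0.1
    v[pick] <- pmin(pmax(v[pick], esv), edv)
  }
  m <- length(p)
  data.frame(time_ms = seq(0, bcl_ms, length.out = m),
             p_lv = p, v_lv = v)
}

#' Write a hemodynamic summary table as CSV
#'
#' One row per quantity, one column per condition, mirroring the usual
#' normal / HF / HF+LVAD report layout.
#'
#' @param summaries named list of `hemo_summary` objects
#' @param path output CSV path
#' @return the table, invisibly
#' @export
write_summary_csv <- function(summaries, path) {
  flat <- lapply(summaries, flatten_summary)
  qs <- Reduce(union, lapply(flat, names))
  tab <- data.frame(quantity = qs)
  for (nm in names(flat)) tab[[nm]] <- unname(flat[[nm]][qs])
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Valve opening durations over one beat
#'
#' For the outflow valves (aortic, pulmonary) and the mitral valve, opening
#' is a discrete event in a diode-valve model and the duration is the time
#' the valve carries flow above a small absolute threshold. The tricuspid
#' valve additionally carries the continuous systemic venous return as a
#' diastasis trickle, so its nominal open time simply tracks diastole
#' length; the physiologically meaningful width of its filling wave is
#' measured instead as the time its flux exceeds half its own peak
#' (`method = "pulse"`).
#'
#' @param beat one-beat data frame with flow columns `q_mi`, `q_ao`,
#'   `q_tr`, `q_pu` and `time_ms`
#' @param method `"threshold"` (time with q > `thresh` mL/s) or `"pulse"`
#'   (time with q > half its peak)
#' @param thresh absolute flow threshold (mL/s) for `"threshold"`
#' @return named numeric vector of durations (ms) for mi, ao, tr, pu
#' @export
valve_open_durations <- function(beat, method = c("threshold", "pulse"),
                                 thresh = 1) {
  method <- match.arg(method)
  span <- diff(range(beat$time_ms))
  vapply(c(mi = "q_mi", ao = "q_ao", tr = "q_tr", pu = "q_pu"),
         function(q) {
           x <- beat[[q]]
           lim <- if (method == "pulse") 0.5 * max(x) else thresh
           mean(x > lim) * span
         }, numeric(1))
}
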
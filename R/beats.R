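## Beat segmentation and per-beat pressure-volume metrics.

#' Segment a trajectory into beats
#'
#' One beat per complete pacing interval covered by the trajectory, windows
#' aligned to the absolute pacing clock (beat onsets at multiples of the
#' period).  End-diastole is the beat onset sample: the protocol is paced,
#' so the onset is unambiguous.
#'
#' @param ts a `cv_timeseries`.
#' @param schedule a `cv_pacing`; its period defines the windows.
#' @return list of `cv_beat` objects: each has `index`, `t`, `p_lv`, `v_lv`,
#'   optional `p_ao`/`q_av`, and flags `is_steady_state` / `is_vco` set from
#'   the trajectory's occlusion boundary (if any).
#' @export
segment_beats <- function(ts, schedule) {
  period <- schedule$beat_period
  t0 <- ts$time[1]; t1 <- ts$time[nrow(ts)]
  if (t1 - t0 < 2 * period - 1e-9)
    stop("trajectory must span at least 2 pacing periods")
  vco_start <- attr(ts, "vco_start") %||% NA_real_
  k0 <- ceiling(t0 / period - 1e-9)
  k1 <- floor(t1 / period + 1e-9) - 1L
  beats <- list()
  for (k in k0:k1) {
    w <- ts[ts$time >= k * period - 1e-9 &
            ts$time < (k + 1) * period - 1e-9, , drop = FALSE]
    if (nrow(w) < 20) next
    is_vco <- is.finite(vco_start) && k * period >= vco_start - 1e-9
    beats[[length(beats) + 1L]] <- structure(list(
      index = k, t = w$time, p_lv = w$p_lv, v_lv = w$v_lv,
      p_ao = w$p_ao, q_av = w$q_av,
      is_steady_state = !is_vco, is_vco = is_vco), class = "cv_beat")
  }
  beats
}

#' Harvest the VCO beat family from a segmented run
#'
#' Takes the last steady-state beat and every occlusion beat until
#' end-diastolic volume has fallen by `edv_drop` (default 40%) of its steady
#' value, or the record ends.  The first occlusion beat is included by
#' default (set `drop_first_vco` to exclude it).
#'
#' @param beats list of `cv_beat` from [segment_beats()].
#' @param edv_drop fractional EDV fall at which harvesting stops.
#' @param drop_first_vco exclude the first occlusion beat from the family.
#' @return list of `cv_beat`.
#' @export
harvest_vco_family <- function(beats, edv_drop = 0.4, drop_first_vco = FALSE) {
  is_vco <- vapply(beats, `[[`, logical(1), "is_vco")
  if (!any(is_vco)) stop("no occlusion beats in this record")
  i_first <- which(is_vco)[1]
  i_start <- max(1L, i_first - 1L)   # last steady beat
  edv0 <- beats[[i_start]]$v_lv[1]
  fam <- list()
  for (i in i_start:length(beats)) {
    if (beats[[i]]$v_lv[1] < (1 - edv_drop) * edv0) break
    fam[[length(fam) + 1L]] <- beats[[i]]
  }
  if (drop_first_vco && length(fam) > 1)
    fam <- fam[-2]   # element 1 is the steady beat, 2 the first VCO beat
  fam
}

#' Scalar pressure-volume metrics of one beat
#'
#' * `EDV` / `LVEDP`: volume and pressure at the beat onset (end-diastole =
#'   pacing onset).
#' * `ESV`: minimum volume.
#' * `Pes`: pressure at aortic-valve closure, detected as the downward
#'   zero-crossing of aortic valve flow; when no flow trace is available the
#'   fallback is the pressure at minimum volume.
#' * `dPdt_max`: maximum centered-difference derivative of LV pressure.
#' * `PP`: aortic pulse pressure over the beat (needs `p_ao`).
#' * `SW`: loop area by the shoelace rule ([stroke_work()]).
#' * `PVA`/`ME`: pressure-volume area and mechanical efficiency, computed
#'   when `v0_for_pva` is supplied (the volume-axis intercept of the ESPVR
#'   fit of the same run; fit first, then compute per-beat PVA).
#'
#' @param beat a `cv_beat`.
#' @param v0_for_pva volume-axis intercept for the potential-energy term, ml
#'   (NA skips PVA and ME).
#' @return list of class `cv_beat_metrics`.
#' @export
beat_metrics <- function(beat, v0_for_pva = NA) {
  t <- beat$t
  if (any(diff(t) <= 0)) stop("beat time axis must be strictly increasing")
  p <- beat$p_lv; v <- beat$v_lv
  n <- length(t)
  edv <- v[1]; esv <- min(v); lvedp <- p[1]
  if (!is.null(beat$q_av) && any(beat$q_av > 0)) {
    i_close <- min(max(which(beat$q_av > 0)) + 1L, n)
  } else {
    i_close <- which.min(v)
  }
  pes <- p[i_close]
  dpdt <- max((p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]))
  pp <- if (!is.null(beat$p_ao)) max(beat$p_ao) - min(beat$p_ao) else NA_real_
  sw <- stroke_work(beat)
  pva <- if (is.na(v0_for_pva)) NA_real_ else pv_area(sw, pes, esv, v0_for_pva)
  me <- if (is.na(pva)) NA_real_ else mechanical_efficiency(sw, pva)
  structure(list(EDV = edv, ESV = esv, SV = edv - esv, SW = sw, Pes = pes,
                 LVEDP = lvedp, PP = pp, dPdt_max = dpdt, PVA = pva, ME = me,
                 Art_ca = dynamic_compliance(edv - esv, pes),
                 is_steady_state = isTRUE(beat$is_steady_state),
                 is_vco = isTRUE(beat$is_vco)),
            class = "cv_beat_metrics")
}

#' Stroke work: pressure-volume loop area
#'
#' Shoelace (polygon) area of the (V, P) loop, orientation-invariant.  An
#' open loop (first and last samples more than 2 ml or 5 mmHg apart) is
#' closed by connecting the last sample back to the first, with a warning.
#'
#' @param beat a `cv_beat` (or any list with `v_lv` and `p_lv`).
#' @return area in mmHg·ml.
#' @export
stroke_work <- function(beat) {
  v <- beat$v_lv; p <- beat$p_lv
  n <- length(v)
  if (abs(v[n] - v[1]) > 2 || abs(p[n] - p[1]) > 5)
    warning(warningCondition(
      "open PV loop; closing last sample to first",
      class = "cv_open_loop_warning"))
  x <- c(v, v[1]); y <- c(p, p[1])
  0.5 * abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)]))
}

#' Pressure-volume area
#'
#' `PVA = SW + PE` with the end-systolic potential-energy triangle
#' `PE = 0.5 * Pes * (ESV - V0)`.  The area under the end-diastolic relation
#' is neglected.  When `ESV <= V0` the potential energy is clamped at zero
#' with a warning.
#'
#' @param SW stroke work, mmHg·ml.
#' @param Pes end-systolic pressure, mmHg (>= 0).
#' @param ESV end-systolic volume, ml.
#' @param v0_for_pva volume-axis intercept, ml.
#' @return PVA in mmHg·ml.
#' @examples
#' pv_area(5000, 100, 60, 10)  # 7500
#' @export
pv_area <- function(SW, Pes, ESV, v0_for_pva) {
  pe <- 0.5 * Pes * (ESV - v0_for_pva)
  if (pe < 0) {
    warning("ESV below the volume-axis intercept; potential energy clamped at 0")
    pe <- 0
  }
  SW + pe
}

#' Mechanical efficiency
#'
#' `ME = 100 * SW / PVA`, percent.
#'
#' @param SW stroke work, mmHg·ml.
#' @param PVA pressure-volume area, mmHg·ml (> 0).
#' @return percent.
#' @examples
#' mechanical_efficiency(5000, 7500)  # 66.67
#' @export
mechanical_efficiency <- function(SW, PVA) {
  if (PVA <= 0) stop("mechanical efficiency undefined for PVA <= 0")
  100 * SW / PVA
}

#' Dynamic arterial compliance
#'
#' `Art-ca = SV / Pes`, the stroke-volume-to-end-systolic-pressure ratio.
#'
#' @param SV stroke volume, ml.
#' @param Pes end-systolic pressure, mmHg (> 0).
#' @return compliance in ml/mmHg.
#' @export
dynamic_compliance <- function(SV, Pes) {
  if (Pes <= 0) stop("dynamic compliance undefined for Pes <= 0")
  SV / Pes
}
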
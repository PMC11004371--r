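## Deterministic synthetic generators: analytic loops and VCO beat families
## with known ground-truth linear structure, so the analysis layer is
## testable without the full simulator.

#' Specification for a synthetic VCO beat family
#'
#' Encodes the four linear relations the family must satisfy, the preload
#' sweep and the (optional) measurement noise.
#'
#' @param espvr_slope,v0 end-systolic relation: `Pes = espvr_slope*(ESV-v0)`.
#' @param prsw_slope,vw stroke-work relation: `SW = prsw_slope*(EDV-vw)`.
#' @param pva_slope,v_pva area relation: `PVA = pva_slope*(EDV-v_pva)`.
#' @param dpdt_slope,v0_dpdt pressure-rise relation:
#'   `dPdt_max = dpdt_slope*(EDV-v0_dpdt)`.
#' @param edv_start,edv_step,n_beats preload sweep: EDV descends from
#'   `edv_start` in steps of `edv_step` for `n_beats` beats.
#' @param noise_sd_fraction Gaussian noise SD as a fraction of each metric
#'   value, in [0, 0.1]; applied to the dependent metrics (Pes, SW,
#'   dP/dt_max, PVA) so the ordinary-least-squares error model holds.
#' @param seed RNG seed; the generator is a pure function of (spec, seed).
#' @return validated list of class `cv_fixture_spec`.
#' @export
fixture_spec <- function(espvr_slope = 1.8, v0 = 15,
                         prsw_slope = 75, vw = 20,
                         pva_slope = 92, v_pva = 25,
                         dpdt_slope = 17, v0_dpdt = 15,
                         edv_start = 120, edv_step = 5, n_beats = 10,
                         noise_sd_fraction = 0, seed = 1L) {
  if (n_beats < 3) stop("n_beats must be >= 3")
  if (edv_step <= 0) stop("edv_step must be > 0")
  if (noise_sd_fraction < 0 || noise_sd_fraction > 0.1)
    stop("noise_sd_fraction must be within [0, 0.1]")
  structure(list(espvr_slope = espvr_slope, v0 = v0,
                 prsw_slope = prsw_slope, vw = vw,
                 pva_slope = pva_slope, v_pva = v_pva,
                 dpdt_slope = dpdt_slope, v0_dpdt = v0_dpdt,
                 edv_start = edv_start, edv_step = edv_step,
                 n_beats = n_beats,
                 noise_sd_fraction = noise_sd_fraction,
                 seed = as.integer(seed)), class = "cv_fixture_spec")
}

#' Rectangular analytic pressure-volume loop
#'
#' A closed rectangle in the (V, P) plane traversed in the physiologic
#' order (fill along the bottom, isovolumic up, eject along the top,
#' isovolumic down); its true loop area is
#' `(p_high - p_low) * (v_high - v_low)` exactly.
#'
#' @param v_low,v_high volume range, ml (`v_high > v_low`).
#' @param p_low,p_high pressure range, mmHg (`p_high > p_low`).
#' @param n_samples total samples around the loop (>= 20).
#' @return a `cv_beat`.
#' @examples
#' b <- make_rect_loop(50, 100, 10, 110, 400)
#' stroke_work(b)  # 5000
#' @export
make_rect_loop <- function(v_low, v_high, p_low, p_high, n_samples = 400) {
  if (v_high <= v_low || p_high <= p_low)
    stop("degenerate ranges: need v_high > v_low and p_high > p_low")
  if (n_samples < 20) stop("n_samples must be >= 20")
  m <- n_samples %/% 4
  seg <- function(a, b, n) seq(a, b, length.out = n + 1)[-(n + 1)]
  v <- c(seg(v_high, v_high, m),      # isovolumic contraction
         seg(v_high, v_low, m),       # ejection at p_high
         seg(v_low, v_low, m),        # isovolumic relaxation
         seg(v_low, v_high, n_samples - 3 * m))  # filling at p_low
  p <- c(seg(p_low, p_high, m),
         seg(p_high, p_high, m),
         seg(p_high, p_low, m),
         seg(p_low, p_low, n_samples - 3 * m))
  structure(list(index = 0L, t = seq(0, 1, length.out = length(v)),
                 p_lv = p, v_lv = v, p_ao = NULL, q_av = NULL,
                 is_steady_state = TRUE, is_vco = FALSE),
            class = "cv_beat")
}

## evaluate with a private, restored RNG state so generators are pure
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic VCO beat-metric family
#'
#' Generates `n_beats` metric sets with EDV descending from `edv_start` by
#' `edv_step`, every metric lying exactly on the spec's four linear
#' relations (plus seeded Gaussian noise): `SW`, `PVA` and `dPdt_max` come
#' straight from their lines, the potential-energy identity
#' `PVA - SW = 0.5*espvr_slope*(ESV - v0)^2` yields a consistent `ESV`, and
#' `Pes = espvr_slope*(ESV - v0)`.
#'
#' @param spec a `cv_fixture_spec`.
#' @return list of `cv_beat_metrics`, reproducible per seed.
#' @export
make_vco_family <- function(spec) {
  stopifnot(inherits(spec, "cv_fixture_spec"))
  edv <- spec$edv_start - (seq_len(spec$n_beats) - 1) * spec$edv_step
  sw <- spec$prsw_slope * (edv - spec$vw)
  pva <- spec$pva_slope * (edv - spec$v_pva)
  dpdt <- spec$dpdt_slope * (edv - spec$v0_dpdt)
  pe <- pva - sw
  if (any(pe < 0))
    stop("inconsistent spec: PVA < SW (negative potential energy)")
  esv <- spec$v0 + sqrt(2 * pe / spec$espvr_slope)
  if (any(esv >= edv))
    stop("inconsistent spec: derived ESV >= EDV")
  pes <- spec$espvr_slope * (esv - spec$v0)
  f <- spec$noise_sd_fraction
  if (f > 0) {
    noisy <- .with_seed(spec$seed, {
      list(pes = pes * (1 + stats::rnorm(length(pes), 0, f)),
           sw = sw * (1 + stats::rnorm(length(sw), 0, f)),
           dpdt = dpdt * (1 + stats::rnorm(length(dpdt), 0, f)),
           pva = pva * (1 + stats::rnorm(length(pva), 0, f)))
    })
    pes <- noisy$pes; sw <- noisy$sw; dpdt <- noisy$dpdt; pva <- noisy$pva
  }
  lapply(seq_along(edv), function(i) {
    structure(list(EDV = edv[i], ESV = esv[i], SV = edv[i] - esv[i],
                   SW = sw[i], Pes = pes[i], LVEDP = NA_real_, PP = NA_real_,
                   dPdt_max = dpdt[i], PVA = pva[i],
                   ME = 100 * sw[i] / pva[i],
                   Art_ca = (edv[i] - esv[i]) / pes[i],
                   is_steady_state = i == 1L, is_vco = i > 1L),
              class = "cv_beat_metrics")
  })
}

#' Single elastance chamber ejecting into an RC afterload
#'
#' A minimal integration fixture: one time-varying-elastance chamber filled
#' from a constant-pressure source through a diode and ejecting through an
#' aortic diode into a two-element (R, C) Windkessel.  Run for several beats
#' to reach its cycle, the last beat is returned; its end-systolic point
#' lies on the `e_max*(V - v0)` line to within a few percent.
#'
#' @param e_max,e_min chamber elastance bounds, mmHg/ml.
#' @param v0 chamber unstressed volume, ml.
#' @param afterload_r Windkessel drain resistance, mmHg·s/ml.
#' @param afterload_c Windkessel compliance, ml/mmHg.
#' @param hr pacing rate, bpm.
#' @param p_fill filling-source pressure, mmHg.
#' @param n_beats beats simulated before the one returned.
#' @return a `cv_beat` (with aortic pressure and valve-flow traces).
#' @export
make_elastance_beat <- function(e_max = 2, e_min = 0.06, v0 = 10,
                                afterload_r = 1.2, afterload_c = 0.8,
                                hr = 80, p_fill = 10, n_beats = 8) {
  period <- 60 / hr
  r_fill <- 0.01; r_av <- 0.005
  deriv <- function(t, y, parms) {
    ph <- (t %% period) / period
    act <- normalized_activation(ph, period)
    e_t <- e_min + (e_max - e_min) * act
    p_lv <- unname(e_t * (y[1] - v0))
    p_art <- unname(y[2] / afterload_c)
    q_in <- max(p_fill - p_lv, 0) / r_fill
    q_av <- max(p_lv - p_art, 0) / r_av
    list(c(q_in - q_av, q_av - p_art / afterload_r),
         c(p_lv = p_lv, p_art = p_art, q_av = q_av))
  }
  y0 <- c(v_lv = v0 + p_fill / e_min * 0.8, v_art = afterload_c * 80)
  times <- seq(0, n_beats * period, by = 0.001)
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-8)
  w <- out[out[, "time"] >= (n_beats - 1) * period - 1e-9, ]
  structure(list(index = n_beats - 1L, t = w[, "time"],
                 p_lv = w[, "p_lv"], v_lv = w[, "v_lv"],
                 p_ao = w[, "p_art"], q_av = w[, "q_av"],
                 is_steady_state = TRUE, is_vco = FALSE),
            class = "cv_beat")
}

#' Per-beat metrics as a data frame
#'
#' Flattens a list of `cv_beat_metrics` into the `metrics.csv` schema used
#' by the command-line interface.
#'
#' @param mets list of `cv_beat_metrics`.
#' @return data.frame, one row per beat.
#' @export
metrics_table <- function(mets) {
  do.call(rbind, lapply(seq_along(mets), function(i) {
    m <- mets[[i]]
    data.frame(beat = i, EDV_ml = m$EDV, ESV_ml = m$ESV, SV_ml = m$SV,
               SW_mmHg_ml = m$SW, Pes_mmHg = m$Pes, LVEDP_mmHg = m$LVEDP,
               PP_mmHg = m$PP, dPdtmax_mmHg_s = m$dPdt_max,
               PVA_mmHg_ml = m$PVA, ME_pct = m$ME,
               ArtCa_ml_mmHg = m$Art_ca, is_vco = m$is_vco)
  }))
}
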
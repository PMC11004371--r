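## Linear least-squares fits of the four pressure-volume relations across a
## VCO beat family, and study-table assembly.

#' Ordinary least squares of a metric on a volume
#'
#' Straight OLS of `y` on `x`; the volume-axis intercept is derived as
#' `-intercept/slope` (the x at which the fitted line crosses zero).
#'
#' @param x volumes, ml (>= 3 points, not constant).
#' @param y metric values.
#' @return list with `slope`, `intercept`, `volume_intercept`, `r_squared`,
#'   `n`.
#' @export
linear_lsq <- function(x, y) {
  if (length(x) < 3) stop("at least 3 points are required")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (max(x) - min(x) < .Machine$double.eps^0.5 * max(1, abs(max(x))))
    stop("degenerate fit: x is constant")
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = b[2], intercept = b[1], volume_intercept = -b[1] / b[2],
       r_squared = r2, n = length(x))
}

.metric_vec <- function(beats, field) {
  vapply(beats, function(b) as.numeric(b[[field]]), numeric(1))
}

.relation_fit <- function(relation, x, y) {
  f <- linear_lsq(x, y)
  structure(list(relation = relation, slope = f$slope,
                 intercept_volume = f$volume_intercept,
                 r_squared = f$r_squared, n_beats = f$n),
            class = "cv_relation_fit")
}

#' @export
print.cv_relation_fit <- function(x, ...) {
  cat(sprintf("%s: slope %.3f, volume intercept %.2f ml, r2 %.4f, n %d\n",
              x$relation, x$slope, x$intercept_volume, x$r_squared,
              x$n_beats))
  invisible(x)
}

#' Fit the end-systolic pressure-volume relationship
#'
#' Regression of end-systolic pressure on end-systolic volume over the VCO
#' family: the slope is the ESPVR (end-systolic elastance) and the
#' volume-axis intercept is V0.
#'
#' @param beats list of `cv_beat_metrics` (a declining-preload family).
#' @return a `cv_relation_fit`.
#' @export
fit_espvr <- function(beats) {
  .relation_fit("ESPVR", .metric_vec(beats, "ESV"), .metric_vec(beats, "Pes"))
}

#' Fit preload recruitable stroke work
#'
#' Regression of stroke work on end-diastolic volume: slope M_w, volume-axis
#' intercept V_w.
#'
#' @inheritParams fit_espvr
#' @return a `cv_relation_fit`.
#' @export
fit_prsw <- function(beats) {
  .relation_fit("PRSW", .metric_vec(beats, "EDV"), .metric_vec(beats, "SW"))
}

#' Fit the dP/dt_max-EDV relation
#'
#' Regression of the peak rate of LV pressure rise on end-diastolic volume;
#' the slope estimates the maximum rate of change of LV elastance
#' (dE/dt_max).
#'
#' @inheritParams fit_espvr
#' @return a `cv_relation_fit`.
#' @export
fit_dpdt_edv <- function(beats) {
  .relation_fit("DPDT_EDV", .metric_vec(beats, "EDV"),
                .metric_vec(beats, "dPdt_max"))
}

#' Fit the PVA-EDV relation
#'
#' Regression of pressure-volume area on end-diastolic volume: slope M_PVA,
#' volume-axis intercept V_PVA.  The beats must already carry PVA values
#' (computed with the V0 of the same run's ESPVR fit).
#'
#' @inheritParams fit_espvr
#' @return a `cv_relation_fit`.
#' @export
fit_pva_edv <- function(beats) {
  pva <- .metric_vec(beats, "PVA")
  if (any(is.na(pva)))
    stop("beats lack PVA values; fit the ESPVR first and recompute metrics ",
         "with its volume intercept")
  .relation_fit("PVA_EDV", .metric_vec(beats, "EDV"), pva)
}

#' Fit all four relations over a VCO family
#'
#' Fits ESPVR, PRSW and dP/dt_max-EDV directly, then uses the ESPVR
#' volume-axis intercept to compute per-beat PVA (when the supplied metrics
#' lack it) and fits PVA-EDV.  This encodes the dependency order: the
#' potential-energy triangle needs V0 from the ESPVR of the same run.
#'
#' @param beats list of `cv_beat_metrics`.
#' @return list with elements `espvr`, `prsw`, `dpdt_edv`, `pva_edv`.
#' @export
fit_relations <- function(beats) {
  espvr <- fit_espvr(beats)
  prsw <- fit_prsw(beats)
  dpdt <- fit_dpdt_edv(beats)
  pva <- .metric_vec(beats, "PVA")
  if (any(is.na(pva))) {
    v0 <- espvr$intercept_volume
    beats <- lapply(beats, function(b) {
      b$PVA <- pv_area(b$SW, b$Pes, b$ESV, v0)
      b
    })
  }
  list(espvr = espvr, prsw = prsw, dpdt_edv = dpdt,
       pva_edv = fit_pva_edv(beats))
}

.study_cols <- c("level", "heart_rate", "EDV_ml", "ESV_ml", "SV_ml",
                 "SW_mmHg_ml", "Pes_mmHg", "LVEDP_mmHg", "dPdtmax_mmHg_s",
                 "PP_mmHg", "ArtCa_ml_mmHg", "ESPVR", "dPdt_EDV", "PRSW",
                 "EDV_PVA", "ME_pct", "flagged")

#' Assemble one study-table row
#'
#' Combines the steady-state beat metrics and the four relation fits into
#' one condition row.  A missing fit or metric set produces a flagged row
#' with NA gaps rather than an error.
#'
#' @param steady a `cv_beat_metrics` for the steady-state beat (or NULL).
#' @param fits list with `espvr`, `prsw`, `dpdt_edv`, `pva_edv` (any may be
#'   missing).
#' @param level,heart_rate condition key.
#' @return one-row `data.frame` with the study-table columns.
#' @export
summarize_condition <- function(steady, fits, level = NA, heart_rate = NA) {
  g <- function(obj, field) {
    if (is.null(obj) || is.null(obj[[field]])) NA_real_
    else as.numeric(obj[[field]])
  }
  row <- data.frame(
    level = level, heart_rate = heart_rate,
    EDV_ml = g(steady, "EDV"), ESV_ml = g(steady, "ESV"),
    SV_ml = g(steady, "SV"), SW_mmHg_ml = g(steady, "SW"),
    Pes_mmHg = g(steady, "Pes"), LVEDP_mmHg = g(steady, "LVEDP"),
    dPdtmax_mmHg_s = g(steady, "dPdt_max"), PP_mmHg = g(steady, "PP"),
    ArtCa_ml_mmHg = g(steady, "Art_ca"),
    ESPVR = g(fits$espvr, "slope"), dPdt_EDV = g(fits$dpdt_edv, "slope"),
    PRSW = g(fits$prsw, "slope"), EDV_PVA = g(fits$pva_edv, "slope"),
    ME_pct = g(steady, "ME"),
    stringsAsFactors = FALSE)
  row$flagged <- anyNA(row[, setdiff(names(row), c("level", "heart_rate"))])
  row
}
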
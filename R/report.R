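## Published reference tables, percent-change convention, and the
## direction/deviation comparison used by the study drivers.

## Published condition-by-metric values (used only for reporting and
## direction checks, never as inputs to any fit or simulation).
.paper_phase1 <- local({
  df <- data.frame(
    level = c("normal", "90pct", "80pct", "60pct", "stiff"),
    heart_rate = 80,
    EDV_ml = c(100.5, 110.9, 116.7, 124.7, 140.1),
    ESV_ml = c(54.1, 61.8, 65.9, 71.4, 87.4),
    SV_ml = c(46.5, 49.1, 50.8, 53.3, 52.7),
    SW_mmHg_ml = c(3830, 4802, 5359, 6150, 7313),
    Pes_mmHg = c(81.7, 97.8, 105.5, 113.7, 133.6),
    LVEDP_mmHg = c(5.0, 5.9, 6.3, 7.0, 8.4),
    dPdtmax_mmHg_s = c(1621, 1859, 1967, 2074, 2057),
    PP_mmHg = c(33.4, 38.8, 44.0, 56.0, 106.6),
    ArtCa_ml_mmHg = c(0.57, 0.50, 0.48, 0.47, 0.39),
    ESPVR = c(1.8, 1.76, 1.75, 1.67, 1.57),
    dPdt_EDV = c(16.9, 17.2, 17.1, 16.7, 14.1),
    PRSW = c(71.4, 81.6, 86.1, 91.4, 94.8),
    EDV_PVA = c(91.7, 108.3, 117.0, 128.5, 154.7),
    ME_pct = c(71.1, 68.2, 67.0, 66.1, 60.5),
    stringsAsFactors = FALSE)
  df
})

.paper_phase2 <- local({
  df <- data.frame(
    level = rep(c("normal", "stiff"), each = 3),
    heart_rate = rep(c(60, 100, 140), 2),
    EDV_ml = c(113.2, 86.9, 75.4, 159.6, 123.2, 75.4),
    ESV_ml = c(54.7, 49.6, 48.6, 92.9, 78.3, 48.6),
    SV_ml = c(58.5, 37.3, 26.7, 66.6, 44.8, 26.7),
    SW_mmHg_ml = c(5078, 2788, 1923, 10322, 5684, 3989),
    Pes_mmHg = c(82.8, 73.3, 72.1, 141.1, 119.4, 72.1),
    LVEDP_mmHg = c(5.5, 5.6, 6.3, 9.9, 8.3, 9.4),
    dPdtmax_mmHg_s = c(1086, 1003, 1050, 1357, 1260, 1403),
    PP_mmHg = c(31.1, 25.4, 22.4, 77.5, 62.4, 56.6),
    ArtCa_ml_mmHg = c(0.71, 0.51, 0.37, 0.47, 0.38, 0.28),
    ESPVR = c(1.75, 1.99, 2.0, 1.45, 1.75, 1.92),
    dPdt_EDV = c(7.3, 10.1, 14.0, 6.5, 9.3, 12.9),
    PRSW = c(82.5, 63.8, 56.5, 118.5, 72.7, 54.6),
    EDV_PVA = c(100.6, 83.2, 79.1, 182.1, 141.0, 131.2),
    ME_pct = c(76.4, 69.9, 62.6, 65.8, 60.7, 53.2),
    stringsAsFactors = FALSE)
  df
})

#' Published reference study tables
#'
#' Read-only copies of the published condition-by-metric values for the two
#' study phases, in the same shape as the tables produced by [run_phase1()]
#' and [run_phase2()].  Used for direction comparison and reporting only —
#' never as inputs to a fit or simulation.
#'
#' @param phase 1 (five compliance levels at 80 bpm) or 2 (normal and stiff
#'   at 60/100/140 bpm).
#' @return data.frame keyed by (`level`, `heart_rate`).
#' @export
paper_study_table <- function(phase) {
  if (phase == 1) .paper_phase1
  else if (phase == 2) .paper_phase2
  else stop("phase must be 1 or 2")
}

#' Percent change between two values
#'
#' `100 * (to - from) / from`, sign preserved — the ratio convention used
#' when reporting condition-to-condition changes.
#'
#' @param from_value baseline (non-zero).
#' @param to_value new value.
#' @return percent.
#' @examples
#' percent_change(54.1, 87.4)   # 61.6
#' @export
percent_change <- function(from_value, to_value) {
  if (any(from_value == 0)) stop("percent change undefined for from_value = 0")
  100 * (to_value - from_value) / from_value
}

## direction of metric m across ordered rows: sign of (last - first)
.trend_sign <- function(v) sign(v[length(v)] - v[1])

#' Compare a computed study table against the published values
#'
#' For every cell present in both tables the signed relative deviation is
#' reported, and for every metric the direction of the condition-to-condition
#' trend (sign of last-minus-first along the published ordering: compliance
#' levels normal to stiff for Phase I, heart rate ascending within each
#' level for Phase II) is compared with the published direction.
#'
#' @param study a `cv_study_table` from [run_phase1()] / [run_phase2()], or
#'   any data.frame with the same key and metric columns.
#' @param phase which published table to compare against; defaults to the
#'   `phase` attribute of `study`.
#' @return list of class `cv_paper_comparison`:
#'   `deviations` (per-cell signed relative deviation),
#'   `directions` (per metric and group: computed and published trend signs
#'   and an `agree` flag), `unmatched` (keys missing from the published
#'   table) and `all_directions_agree`.
#' @export
compare_to_paper <- function(study, phase = attr(study, "phase")) {
  if (is.null(phase)) stop("phase not given and not carried by the table")
  ref <- paper_study_table(phase)
  metrics <- setdiff(intersect(names(ref), names(study)),
                     c("level", "heart_rate"))
  key <- function(d) paste(d$level, d$heart_rate, sep = "@")
  unmatched <- setdiff(key(study), key(ref))
  common <- intersect(key(ref), key(study))
  ref_i <- match(common, key(ref))
  stu_i <- match(common, key(study))
  dev <- data.frame(level = ref$level[ref_i],
                    heart_rate = ref$heart_rate[ref_i])
  for (m in metrics)
    dev[[m]] <- (study[[m]][stu_i] - ref[[m]][ref_i]) / ref[[m]][ref_i]
  ## trend groups: phase 1 = ordered levels at 80 bpm; phase 2 = ordered
  ## heart rates within each level
  groups <- if (phase == 1) {
    list(all = order(match(ref$level[ref_i], .compliance_levels$level)))
  } else {
    lapply(split(seq_along(ref_i), ref$level[ref_i]),
           function(ix) ix[order(ref$heart_rate[ref_i][ix])])
  }
  dirs <- NULL
  for (gname in names(groups)) {
    ix <- groups[[gname]]
    if (length(ix) < 2) next
    for (m in metrics) {
      ours <- .trend_sign(study[[m]][stu_i][ix])
      theirs <- .trend_sign(ref[[m]][ref_i][ix])
      dirs <- rbind(dirs, data.frame(
        metric = m, group = gname, computed = ours, published = theirs,
        agree = !is.na(ours) && ours == theirs,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(deviations = dev, directions = dirs, unmatched = unmatched,
                 all_directions_agree = all(dirs$agree)),
            class = "cv_paper_comparison")
}

#' @export
print.cv_paper_comparison <- function(x, ...) {
  n <- nrow(x$directions)
  ok <- sum(x$directions$agree)
  cat(sprintf("direction agreement: %d/%d trends\n", ok, n))
  if (ok < n) {
    bad <- x$directions[!x$directions$agree, ]
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  disagrees: %s [%s]\n", bad$metric[i], bad$group[i]))
  }
  if (length(x$unmatched))
    cat("unmatched keys:", paste(x$unmatched, collapse = ", "), "\n")
  invisible(x)
}
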
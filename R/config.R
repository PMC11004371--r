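## Model configuration: chamber and vascular parameters, validation,
## parameter packing for the compiled right-hand side.

#' Default closed-loop cardiovascular model configuration
#'
#' Builds the packaged human-scaled configuration: four time-varying
#' elastance chambers, an aortic-arch proximal Windkessel element, a lumped
#' systemic artery, five parallel distal systemic beds, lumped systemic and
#' thoracic veins and a two-compartment pulmonary loop.  The arterial side
#' sums to an equivalent compliance C_A = 0.7 ml/mmHg and reduces to a total
#' peripheral resistance R_T = 1.28 mmHg·s/ml (the "normal" vascular-aging
#' setting); chamber elastances and the activation waveform are calibrated so
#' the paced steady state at 80 bpm produces aortic pressures of
#' approximately 120/80 mmHg with a 40 mmHg pulse pressure.
#'
#' @param heart_rate pacing rate, bpm (30-220).
#' @param total_blood_volume total blood volume, ml.
#' @param force_freq_gain linear gain applied to ventricular E_max as
#'   `1 + gain*(HR-80)/80`; the explicit force-frequency knob.
#' @param vco vena caval occlusion schedule, see [vco_params()].
#' @param solver list with elements `rel_tol`, `abs_tol`, `sample_dt`
#'   (output sampling interval, s).
#' @return An object of class `cv_config`: a list with elements `heart_rate`,
#'   `total_blood_volume`, `chambers` (data frame, rows la/lv/ra/rv),
#'   `compartments` (data frame, one row per vascular compartment),
#'   `valves`, `activation`, `R_T`, `autonomic_blockade`, `solver`, `vco`.
#' @examples
#' cfg <- model_config()
#' equivalent_arterial_compliance(cfg)  # 0.7
#' total_peripheral_resistance(cfg)     # 1.28
#' @export
model_config <- function(heart_rate = 80,
                         total_blood_volume = 5300,
                         force_freq_gain = 0.3,
                         vco = vco_params(start_time = Inf,
                                          resistance_multiplier = 1),
                         solver = list(rel_tol = 1e-6, abs_tol = 1e-6,
                                       sample_dt = 0.001)) {
  chambers <- data.frame(
    row.names = .chamber_names,
    E_max = c(0.25, 2.6, 0.20, 0.8),
    E_min = c(0.12, 0.055, 0.10, 0.045),
    V0 = c(5, 10, 5, 10),
    onset_advance_s = c(0.16, 0, 0.16, 0),
    sysk_scale = c(0.7, 1, 0.7, 1)
  )

  fr <- .distal_fractions
  r_parallel <- 1.265   # parallel reduction of the five branches, mmHg·s/ml
  in_share <- 0.3       # arterial (inflow) share of each branch resistance
  compartments <- data.frame(
    name = .comp_names,
    compliance = c(0.44, 0.22, 0.004, 0.006, 0.012, 0.012, 0.006,
                   60, 15, 4, 8),
    resistance_out = c(0.015, NA,
                       (1 - in_share) * r_parallel / unname(fr),
                       0.25, 0.015, 0.08, 0.01),
    resistance_in = c(NA, NA, in_share * r_parallel / unname(fr),
                      NA, NA, NA, NA),
    unstressed_volume = c(60, 150, 20, 50, 120, 250, 60, 2210, 250, 100, 350),
    stringsAsFactors = FALSE
  )

  cfg <- structure(list(
    heart_rate = heart_rate,
    total_blood_volume = total_blood_volume,
    chambers = chambers,
    compartments = compartments,
    valves = c(mitral = 0.003, aortic = 0.005, tricuspid = 0.003,
               pulmonic = 0.005),
    activation = list(
      sys_k = 0.7,          # systole = sys_k*sqrt(60/HR), s
      max_fraction = 0.66,  # systole never exceeds this fraction of period
      peak_fraction = 0.78, # peak elastance at this fraction of systole
      rise1_level = 0.30,   # activation after the fast initial rise
      atrial_advance = 0.16,# s the atria lead the ventricles
      force_freq_gain = force_freq_gain,
      p_floor = -5          # chamber pressure floor, mmHg
    ),
    R_T = 1.28,
    autonomic_blockade = TRUE,
    solver = solver,
    vco = vco
  ), class = "cv_config")
  validate_config(cfg)
  cfg
}

#' Vena caval occlusion schedule
#'
#' The occlusion is a time-based rise of the thoracic-vein outflow
#' resistance (the venous return path into the right atrium).  With the
#' exponential profile the resistance follows a geometric ramp,
#' `baseline * multiplier^(t'/ramp)`, reaching `baseline * multiplier` at the
#' end of the ramp and staying there.
#'
#' @param start_time occlusion onset, s (Inf disables it).
#' @param ramp_duration ramp length, s.
#' @param resistance_multiplier factor applied to the baseline resistance at
#'   full occlusion; must be >= 10 when the occlusion is active so preload
#'   actually falls.
#' @param profile `"exponential"` (geometric ramp) or `"linear"`.
#' @return list with the validated fields.
#' @export
vco_params <- function(start_time = Inf, ramp_duration = 8,
                       resistance_multiplier = 100,
                       profile = c("exponential", "linear")) {
  profile <- match.arg(profile)
  if (ramp_duration <= 0) stop("ramp_duration must be > 0")
  if (is.finite(start_time) && resistance_multiplier > 1 &&
      resistance_multiplier < 10)
    stop("resistance_multiplier must be >= 10 for an effective occlusion")
  list(start_time = start_time, ramp_duration = ramp_duration,
       resistance_multiplier = resistance_multiplier, profile = profile)
}

#' Validate a model configuration
#'
#' Checks the invariants: positive compliances and resistances, chamber
#' `E_max > E_min > 0`, heart rate within the pacing range 30-220 bpm, and
#' that the stored total peripheral resistance `R_T` agrees with the
#' series/parallel reduction of the compartment resistances to within 1%.
#'
#' @param config a `cv_config` object.
#' @return the config, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cv_config"))
  if (config$heart_rate < 30 || config$heart_rate > 220)
    stop("heart_rate must be within [30, 220] bpm")
  ch <- config$chambers
  if (!all(ch$E_max > ch$E_min) || !all(ch$E_min > 0))
    stop("chamber elastances must satisfy E_max > E_min > 0")
  cp <- config$compartments
  if (!identical(cp$name, .comp_names))
    stop("compartments must be the 11 packaged compartments, in order")
  if (!all(cp$compliance > 0))
    stop("all compartment compliances must be > 0")
  if (!all(stats::na.omit(c(cp$resistance_out, cp$resistance_in)) > 0))
    stop("all compartment resistances must be > 0")
  if (config$total_blood_volume <= 0)
    stop("total_blood_volume must be > 0")
  rt <- total_peripheral_resistance(config)
  if (abs(rt - config$R_T) / config$R_T > 0.01)
    stop(sprintf(paste0("stored R_T (%.4f) disagrees with the resistance",
                        " reduction (%.4f) by more than 1%%"),
         config$R_T, rt))
  invisible(config)
}

#' Equivalent arterial compliance of a configuration
#'
#' The parallel combination of the arterial compartments (aortic arch,
#' systemic artery and the five distal beds), i.e. the sum of their
#' compliances.  This is the quantity the graded vascular-aging settings
#' target (C_A).
#'
#' @param config a `cv_config`.
#' @return compliance in ml/mmHg.
#' @export
equivalent_arterial_compliance <- function(config) {
  cp <- config$compartments
  sum(cp$compliance[cp$name %in% .arterial_comps])
}

#' Total peripheral resistance of a configuration
#'
#' Series/parallel reduction of the arterial path: aortic-arch outflow
#' resistance in series with the parallel combination of the five distal
#' branches (each branch = inflow + outflow resistance in series).
#'
#' @param config a `cv_config`.
#' @return resistance in mmHg·s/ml.
#' @export
total_peripheral_resistance <- function(config) {
  cp <- config$compartments
  r_aa <- cp$resistance_out[cp$name == "aortic_arch"]
  idx <- match(.distal_comps, cp$name)
  branch <- cp$resistance_in[idx] + cp$resistance_out[idx]
  r_aa + 1 / sum(1 / branch)
}

#' @export
print.cv_config <- function(x, ...) {
  cat("Closed-loop cardiovascular model configuration\n")
  cat(sprintf("  heart rate: %g bpm; total blood volume: %g ml\n",
              x$heart_rate, x$total_blood_volume))
  cat(sprintf("  C_A = %.3f ml/mmHg; R_T = %.3f mmHg.s/ml\n",
              equivalent_arterial_compliance(x),
              total_peripheral_resistance(x)))
  cat(sprintf("  autonomic blockade: %s; VCO multiplier: %g\n",
              x$autonomic_blockade, x$vco$resistance_multiplier))
  invisible(x)
}

## Pack a cv_config into the 64-double parameter vector expected by the
## compiled RHS (src/cvmodel.c); 65 doubles.  Layout must stay in lockstep with the C
## macros.
.pack_parms <- function(config) {
  ch <- config$chambers
  cp <- config$compartments
  act <- config$activation
  idx <- match(.distal_comps, cp$name)
  vco <- config$vco
  p <- c(config$heart_rate, act$force_freq_gain, act$atrial_advance,
         act$sys_k, act$p_floor,
         ch$E_max, ch$E_min, ch$V0,
         0.7,                               # atrial systole-duration scale
         cp$compliance, cp$unstressed_volume,
         config$valves[["mitral"]], config$valves[["aortic"]],
         config$valves[["tricuspid"]], config$valves[["pulmonic"]],
         cp$resistance_out[cp$name == "aortic_arch"],
         cp$resistance_in[idx], cp$resistance_out[idx],
         cp$resistance_out[cp$name == "systemic_vein"],
         cp$resistance_out[cp$name == "thoracic_vein"],
         cp$resistance_out[cp$name == "pulmonary_artery"],
         cp$resistance_out[cp$name == "pulmonary_vein"],
         if (is.finite(vco$start_time)) vco$start_time else 1e30,
         vco$ramp_duration, vco$resistance_multiplier,
         act$peak_fraction, act$rise1_level,
         as.numeric(identical(vco$profile, "linear")))
  stopifnot(length(p) == 65L)
  p
}

#' Default initial state for a configuration
#'
#' Distributes the total blood volume over chambers and compartments from a
#' physiologic pressure guess; any residual volume is placed in the
#' systemic-vein reservoir so the total matches
#' `config$total_blood_volume` exactly.
#'
#' @param config a `cv_config`.
#' @return a named numeric vector of 15 volumes (ml): the four chambers
#'   (la, lv, ra, rv) followed by the 11 compartments.
#' @export
initial_state <- function(config) {
  cp <- config$compartments
  p_guess <- c(aortic_arch = 92, systemic_artery = 90, coronary = 87,
               cerebral = 87, skeletal_muscle = 87, splanchnic = 87,
               extrasplanchnic = 87, systemic_vein = 9, thoracic_vein = 6,
               pulmonary_artery = 15, pulmonary_vein = 8.5)
  v_comp <- cp$unstressed_volume + cp$compliance * p_guess[cp$name]
  v_ch <- c(la = 50, lv = 120, ra = 50, rv = 125)
  y <- c(v_ch, stats::setNames(v_comp, cp$name))
  y[["systemic_vein"]] <- y[["systemic_vein"]] +
    (config$total_blood_volume - sum(y))
  if (y[["systemic_vein"]] < 0)
    stop("total_blood_volume too small to fill the circuit")
  y
}

#' Read / write a model configuration as YAML
#'
#' The YAML schema is versioned (`schema: 1`) and stores every tunable field
#' of the configuration; fields omitted from the file keep their packaged
#' defaults.
#'
#' @param path file path.
#' @param config a `cv_config` (for writing).
#' @return `read_config()` returns a `cv_config`; `write_config()` returns
#'   the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$schema) && raw$schema != 1)
    stop("unsupported config schema version: ", raw$schema)
  cfg <- model_config()
  scalar <- intersect(names(raw),
                      c("heart_rate", "total_blood_volume", "R_T"))
  cfg[scalar] <- raw[scalar]
  if (!is.null(raw$activation))
    cfg$activation[names(raw$activation)] <- raw$activation
  if (!is.null(raw$valves))
    cfg$valves[names(raw$valves)] <- unlist(raw$valves)
  if (!is.null(raw$vco))
    cfg$vco[names(raw$vco)] <- raw$vco
  if (!is.null(raw$solver))
    cfg$solver[names(raw$solver)] <- raw$solver
  if (!is.null(raw$chambers))
    for (nm in names(raw$chambers))
      cfg$chambers[nm, names(raw$chambers[[nm]])] <- raw$chambers[[nm]]
  if (!is.null(raw$compartments))
    for (nm in names(raw$compartments)) {
      i <- match(nm, cfg$compartments$name)
      if (is.na(i)) stop("unknown compartment in config file: ", nm)
      for (fld in names(raw$compartments[[nm]]))
        cfg$compartments[i, fld] <- raw$compartments[[nm]][[fld]]
    }
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  cp <- config$compartments
  comp_list <- lapply(seq_len(nrow(cp)), function(i) {
    out <- list(compliance = cp$compliance[i],
                resistance_out = cp$resistance_out[i],
                unstressed_volume = cp$unstressed_volume[i])
    if (!is.na(cp$resistance_in[i])) out$resistance_in <- cp$resistance_in[i]
    out
  })
  names(comp_list) <- cp$name
  ch <- config$chambers
  ch_list <- lapply(rownames(ch), function(nm) as.list(ch[nm, ]))
  names(ch_list) <- rownames(ch)
  yaml::write_yaml(list(
    schema = 1,
    heart_rate = config$heart_rate,
    total_blood_volume = config$total_blood_volume,
    R_T = config$R_T,
    chambers = ch_list,
    compartments = comp_list,
    valves = as.list(config$valves),
    activation = config$activation,
    solver = config$solver,
    vco = config$vco
  ), path)
  invisible(path)
}
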
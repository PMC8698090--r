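#' Energetics configuration
#'
#' Parameters of the three heart-rate-derived indices:
#' \deqn{EE = a \cdot HR^{b}} in J kg\eqn{^{-1}} min\eqn{^{-1}} with
#' defaults \eqn{a = 0.0566}, \eqn{b = 1.9955};
#' \deqn{COT = (HR - HR_0)\, kg^{-1} m^{-1} \times 10^{3}} and
#' \deqn{P_{met} = (HR - HR_0)\, min^{-1} kg^{-1} \times 10^{3}} with a
#' resting baseline \eqn{HR_0 = 35} beats/min.
#'
#' The printed COT unit string is dimensionally ambiguous (beats per minute
#' divided by a distance needs a time basis), so two conventions are
#' implemented and always named in outputs:
#' \describe{
#'   \item{`dimensional`}{total beats above baseline over the segment per kg
#'     per metre: `(HR - HR0) * duration_min / (mass * distance) * scale`.
#'     Time-consistent; the default.}
#'   \item{`paper_numeric`}{beats/min above baseline divided by speed (m/s)
#'     and mass: `(HR - HR0) / (speed * mass) * scale`. Reproduces the
#'     printed magnitudes (tens at gallop for ~513 kg carried mass).}
#' }
#'
#' @param baseline_hr_bpm Resting baseline heart rate, default 35.
#' @param ee_coeff,ee_exp Coefficient and exponent of the EE power law.
#' @param scale_factor Multiplier applied to COT and Pmet, default 1000 (the
#'   "x 10^3" of the printed unit; Pmet magnitudes in the hundreds are only
#'   reachable with the same factor). With `scale_factor = 1` the operations
#'   return the literal formulas.
#' @param cot_mode `"dimensional"` or `"paper_numeric"`.
#' @param ee_on `"samples"` (default: segment EE is the mean of per-sample
#'   EE over the full 1 Hz stream) or `"mean_hr"` (EE of the segment-mean
#'   HR).
#' @return An `energetics_config` object.
#' @export
energetics_config <- function(baseline_hr_bpm = 35, ee_coeff = 0.0566,
                              ee_exp = 1.9955, scale_factor = 1000,
                              cot_mode = c("dimensional", "paper_numeric"),
                              ee_on = c("samples", "mean_hr")) {
  cot_mode <- match.arg(cot_mode)
  ee_on <- match.arg(ee_on)
  if (ee_coeff <= 0 || ee_exp <= 0 || baseline_hr_bpm < 0 ||
      scale_factor <= 0) {
    stop("invalid energetics parameters", call. = FALSE)
  }
  structure(list(baseline_hr_bpm = baseline_hr_bpm, ee_coeff = ee_coeff,
                 ee_exp = ee_exp, scale_factor = scale_factor,
                 cot_mode = cot_mode, ee_on = ee_on),
            class = "energetics_config")
}

#' Heart-rate-derived energy expenditure
#'
#' `EE = coeff * HR^exp`, J per kg per min. Strictly increasing in HR and
#' zero at HR 0.
#'
#' @param hr_bpm Non-negative heart rate(s), beats/min (vectorised).
#' @param config An `energetics_config`.
#' @return EE in J/kg/min.
#' @examples
#' energy_expenditure(100) # ~554.4
#' @export
energy_expenditure <- function(hr_bpm, config = energetics_config()) {
  if (any(!is.finite(hr_bpm)) || any(hr_bpm < 0)) {
    stop("heart rate must be finite and non-negative", call. = FALSE)
  }
  config$ee_coeff * hr_bpm ^ config$ee_exp
}

.beats_above <- function(mean_hr_bpm, config) {
  x <- mean_hr_bpm - config$baseline_hr_bpm
  if (any(x < 0)) {
    warning("mean HR below baseline (", config$baseline_hr_bpm,
            " bpm); clamped to 0", call. = FALSE)
    x <- pmax(x, 0)
  }
  x
}

#' Cost of transport
#'
#' Beats above the resting baseline normalised per kg carried mass per metre
#' travelled, times `scale_factor`. See [energetics_config()] for the two
#' unit conventions; values below baseline clamp to zero with a warning.
#'
#' @param mean_hr_bpm Segment mean heart rate, beats/min.
#' @param mass_kg Total carried mass (> 0), kg.
#' @param distance_m Segment distance (> 0; `dimensional` mode), m.
#' @param duration_s Segment duration (`dimensional` mode), s.
#' @param mean_speed_mps Segment mean speed (> 0; `paper_numeric` mode).
#' @param config An `energetics_config`.
#' @return Scaled COT.
#' @export
cost_of_transport <- function(mean_hr_bpm, mass_kg, distance_m = NULL,
                              duration_s = NULL, mean_speed_mps = NULL,
                              config = energetics_config()) {
  if (any(mass_kg <= 0)) stop("mass must be positive", call. = FALSE)
  beats <- .beats_above(mean_hr_bpm, config)
  if (config$cot_mode == "dimensional") {
    if (is.null(distance_m) || is.null(duration_s) || any(distance_m <= 0) ||
        any(duration_s <= 0)) {
      stop("dimensional COT needs positive distance_m and duration_s",
           call. = FALSE)
    }
    beats * (duration_s / 60) / (mass_kg * distance_m) * config$scale_factor
  } else {
    if (is.null(mean_speed_mps) || any(mean_speed_mps <= 0)) {
      stop("paper_numeric COT needs positive mean_speed_mps", call. = FALSE)
    }
    beats / (mean_speed_mps * mass_kg) * config$scale_factor
  }
}

#' Metabolic power
#'
#' Beats/min above the resting baseline per kg carried mass, times
#' `scale_factor`. Clamped at zero below baseline.
#'
#' @inheritParams cost_of_transport
#' @return Scaled Pmet.
#' @examples
#' metabolic_power(135, 500) # 200
#' @export
metabolic_power <- function(mean_hr_bpm, mass_kg,
                            config = energetics_config()) {
  if (any(mass_kg <= 0)) stop("mass must be positive", call. = FALSE)
  .beats_above(mean_hr_bpm, config) / mass_kg * config$scale_factor
}

# Assign each sample to a race epoch: epoch i runs up to the onset of the
# approach to race i+1, found by walking back from race i+1's start through
# contiguous non-walk labels. The rest after race i thereby belongs to race
# i and the approach trot to race i+1, matching the per-race pace rows of
# the study's tables. Samples before the first race fold into epoch 1.
.race_epoch <- function(t_s, races, labels) {
  onset <- vapply(races$start_s[-1L], function(st) {
    j <- match(TRUE, t_s >= st)
    while (j > 1L && labels[j - 1L] != "walk") j <- j - 1L
    t_s[j]
  }, numeric(1L))
  findInterval(t_s, c(-Inf, onset, Inf))
}

#' Per race-by-gait energetics summary
#'
#' Splits the session into race epochs (each race plus its surrounding
#' recovery, see Details), crosses them with gait labels, and reports per
#' cell: sample count, duration, distance, mean HR, mean speed, EE, COT and
#' Pmet. Session totals (rows with `race == 0`, `gait == "total"`) are
#' computed identically over all non-transition samples. Transition samples
#' are excluded from gait cells and totals but counted in the
#' `transition_s` attribute.
#'
#' EE per cell is by default the mean of per-sample EE over the cell's 1 Hz
#' stream (`ee_on = "samples"`); COT and Pmet use the cell's mean HR, the
#' subject's total carried mass, and the cell's distance/duration/mean
#' speed.
#'
#' @details Race epoch `i` spans from the detected start of race `i` to the
#'   start of race `i + 1` (last epoch to session end; samples before the
#'   first race fold into epoch 1), so each 5-min rest is attributed to the
#'   race it follows.
#'
#' @param session An `exercise_session`.
#' @param labels Gait labels aligned to samples.
#' @param races Race table from [detect_races()]; at least one race.
#' @param config An `energetics_config`.
#' @return A data.frame of class `energetics_summary`, one row per
#'   race-by-gait cell plus total rows; columns `subject_id`, `role`,
#'   `race`, `gait`, `n_samples`, `duration_s`, `distance_m`,
#'   `mean_hr_bpm`, `mean_speed_mps`, `ee_J_per_kg_min`, `cot_scaled`,
#'   `pmet_scaled`. Attributes record the COT mode and transition seconds.
#' @export
summarize_session <- function(session, labels, races,
                              config = energetics_config()) {
  stopifnot(inherits(session, "exercise_session"))
  s <- session$samples
  if (length(labels) != nrow(s)) {
    stop("labels not aligned to samples", call. = FALSE)
  }
  if (is.null(races) || nrow(races) == 0L) {
    stop("no races detected; cannot summarize a VST session", call. = FALSE)
  }
  mass <- total_carried_mass(session$metadata)
  epoch <- .race_epoch(s$t_s, races, labels)
  keep <- labels != "transition"
  cell_stats <- function(idx, race_id, gait) {
    mean_hr <- mean(s$hr_bpm[idx])
    mean_v <- mean(s$speed_mps[idx])
    dur <- length(idx) # 1 Hz samples present
    dist <- sum(s$speed_mps[idx]) # integrate speed over member samples
    ee <- if (config$ee_on == "samples") {
      mean(energy_expenditure(s$hr_bpm[idx], config))
    } else {
      energy_expenditure(mean_hr, config)
    }
    cot <- if (config$cot_mode == "dimensional") {
      if (dist > 0) {
        cost_of_transport(mean_hr, mass, distance_m = dist,
                          duration_s = dur, config = config)
      } else NA_real_
    } else {
      if (mean_v > 0) {
        cost_of_transport(mean_hr, mass, mean_speed_mps = mean_v,
                          config = config)
      } else NA_real_
    }
    data.frame(subject_id = session$metadata$subject_id,
               role = session$metadata$role, race = race_id, gait = gait,
               n_samples = length(idx), duration_s = dur, distance_m = dist,
               mean_hr_bpm = mean_hr, mean_speed_mps = mean_v,
               ee_J_per_kg_min = ee, cot_scaled = cot,
               pmet_scaled = metabolic_power(mean_hr, mass, config))
  }
  rows <- list()
  for (r in sort(unique(epoch))) {
    for (g in c("walk", "trot", "gallop")) {
      idx <- which(epoch == r & labels == g)
      if (length(idx) > 0L) {
        rows[[length(rows) + 1L]] <- cell_stats(idx, r, g)
      }
    }
  }
  idx_all <- which(keep)
  if (length(idx_all) > 0L) {
    rows[[length(rows) + 1L]] <- cell_stats(idx_all, 0L, "total")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, cot_mode = config$cot_mode,
            transition_s = sum(!keep),
            class = c("energetics_summary", "data.frame"))
}

#' Fraction of samples per heart-rate zone
#'
#' Zones are the half-open intervals defined by `zone_bounds`; a bound `b`
#' separates `hr < b` from `hr >= b`. Fractions sum to 1.
#'
#' @param session An `exercise_session`.
#' @param zone_bounds Strictly increasing vector of bounds, beats/min.
#' @return Named numeric vector of fractions, one per zone.
#' @examples
#' # share of work below/above the 150 bpm aerobic marker:
#' # hr_zone_fractions(session, 150)
#' @export
hr_zone_fractions <- function(session, zone_bounds) {
  stopifnot(inherits(session, "exercise_session"))
  if (length(zone_bounds) < 1L || is.unsorted(zone_bounds, strictly = TRUE)) {
    stop("zone_bounds must be strictly increasing", call. = FALSE)
  }
  hr <- session$samples$hr_bpm
  zone <- findInterval(hr, zone_bounds) + 1L
  counts <- tabulate(zone, nbins = length(zone_bounds) + 1L)
  lo <- c("-Inf", format(zone_bounds))
  hi <- c(format(zone_bounds), "Inf")
  stats::setNames(counts / length(hr), paste0("[", lo, ",", hi, ")"))
}
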
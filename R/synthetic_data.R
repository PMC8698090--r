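#' Synthetic VST generator configuration
#'
#' Describes the simulated vaquejada simulation test: a warm-up walk, then
#' `n_races` blocks of approach trot, gallop, deceleration and walking rest,
#' with role-specific per-gait heart-rate and speed targets and a
#' role-specific lactate kinetic model. The default preset `"coelho2021"`
#' parameterises the generator from the study's published group means:
#' per-gait HR/speed targets are the across-race means of the printed
#' per-race values, lactate parameters reproduce the printed six-timepoint
#' group curves, and masses are the published role means (428 kg horse,
#' 75/72.5 kg rider for PH/HH, 10 kg tack).
#'
#' Heart-rate dynamics are first-order relaxations toward a per-block
#' asymptote that is solved in closed form so that the block's *mean* equals
#' the gait target (the published values are segment means, not asymptotes).
#' Recovery time constants are role-specific -- pull horses recover more
#' slowly after the gallop -- which builds in the reported direction of the
#' below-150-bpm time contrast between roles. In the noise-free limit
#' (`hr_subject_sd = hr_jitter_sd = 0`, `tau_rise = tau_recovery = 0`) the
#' generated HR equals the target exactly within each gait block.
#'
#' @param n_pairs Number of PH/HH pairs, default 4 (the study's eight
#'   horses).
#' @param n_races Races per session, default 3.
#' @param race_duration_s Integer range the gallop duration is drawn from,
#'   default `c(40, 50)` seconds.
#' @param race_distance_m Nominal track length range, default `c(130, 150)`
#'   (recorded in manifests; the realised distance follows speed x duration
#'   -- see the package vignette).
#' @param rest_s Walking rest between races, default 300 s.
#' @param warmup_s Warm-up walk before race 1, default 60 s.
#' @param trot_s Approach trot before each gallop, default 15 s.
#' @param decel_s Deceleration ramp after each gallop, default 5 s.
#' @param hr_targets Named list `PH`/`HH`, each `c(walk=, trot=, gallop=)`
#'   mean HR targets in beats/min.
#' @param speed_targets Same structure, mean speeds in m/s.
#' @param speed_sd Named vector `c(walk=, trot=, gallop=)` of within-block
#'   speed SDs (draws are clipped inside the gait band).
#' @param hr_subject_sd Between-subject SD added to every HR target, bpm.
#' @param hr_jitter_sd Per-sample Gaussian HR jitter, bpm.
#' @param tau_rise Time constant of HR rise (s), default 2.
#' @param tau_recovery Named vector `c(PH=, HH=)` of recovery time constants
#'   (s), default `c(PH = 180, HH = 45)`.
#' @param lactate Named list `PH`/`HH`, each with `baseline` (T0, mmol/L),
#'   `increments` (per-race rises at T1..T3), `rest_level` (late-recovery
#'   asymptote; the decay target, which the printed 240-min values place
#'   below T0), `half_life_min`, and `cv` (between-subject coefficient of
#'   variation).
#' @param seed Integer master seed; per-subject substreams are derived from
#'   it so cohorts are stable under reordering.
#' @return A `vst_config` object.
#' @export
vst_config <- function(n_pairs = 4L, n_races = 3L,
                       race_duration_s = c(40L, 50L),
                       race_distance_m = c(130, 150),
                       rest_s = 300L, warmup_s = 60L, trot_s = 15L,
                       decel_s = 5L,
                       hr_targets = list(
                         PH = c(walk = 105.37, trot = 135.55,
                                gallop = 185.24),
                         HH = c(walk = 121.25, trot = 156.36,
                                gallop = 179.11)),
                       speed_targets = list(
                         PH = c(walk = 0.97, trot = 3.12, gallop = 6.88),
                         HH = c(walk = 1.18, trot = 2.88, gallop = 6.65)),
                       speed_sd = c(walk = 0.25, trot = 0.4, gallop = 0.35),
                       hr_subject_sd = 1.5, hr_jitter_sd = 2,
                       tau_rise = 2,
                       tau_recovery = c(PH = 180, HH = 45),
                       lactate = list(
                         PH = list(baseline = 2.2,
                                   increments = c(5.8, 1.5, 1.1),
                                   rest_level = 1.8, half_life_min = 15.5,
                                   cv = 0.15),
                         HH = list(baseline = 2.1,
                                   increments = c(3.5, 0.7, 0.4),
                                   rest_level = 2.3, half_life_min = 5,
                                   cv = 0.15)),
                       seed = 1L) {
  stopifnot(n_pairs >= 1L, n_races >= 1L,
            length(race_duration_s) == 2L,
            race_duration_s[1L] <= race_duration_s[2L],
            race_duration_s[1L] >= 1L,
            rest_s >= 1L, warmup_s >= 1L, trot_s >= 1L, decel_s >= 1L,
            hr_subject_sd >= 0, hr_jitter_sd >= 0, tau_rise >= 0,
            all(tau_recovery >= 0), all(speed_sd >= 0))
  for (role in c("PH", "HH")) {
    if (!all(c("walk", "trot", "gallop") %in% names(hr_targets[[role]])) ||
        !all(c("walk", "trot", "gallop") %in%
               names(speed_targets[[role]]))) {
      stop("hr_targets and speed_targets need walk/trot/gallop for ", role,
           call. = FALSE)
    }
    lc <- lactate[[role]]
    if (lc$baseline <= 0 || lc$rest_level <= 0 || lc$half_life_min < 0 ||
        any(lc$increments < 0) || lc$cv < 0) {
      stop("invalid lactate parameters for ", role, call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "vst_config")
}

#' The study-mean preset
#'
#' Convenience wrapper for [vst_config()] with its published-group-means
#' defaults; `name` exists so manifests can record which preset ran.
#'
#' @param name Preset name; only `"coelho2021"` is defined.
#' @param ... Overrides passed to [vst_config()].
#' @return A `vst_config`.
#' @export
vst_preset <- function(name = "coelho2021", ...) {
  name <- match.arg(name)
  cfg <- vst_config(...)
  attr(cfg, "preset") <- name
  cfg
}

# Derive a deterministic per-subject RNG substream from the master seed, so
# a cohort is reproducible and stable under subject reordering. Kept well
# below 2^31.
.substream <- function(seed, role, subject_index) {
  off <- if (role == "PH") 1L else 2L
  as.integer((abs(seed) %% 1000003) * 1009 + off * 65537 +
               subject_index * 7919) %% 2147483399L
}

# First-order relaxation of length n from h0 whose sample mean equals
# `target`: h_t = A + (h0 - A) r^t with r = exp(-1/tau) and the asymptote A
# solved from mean(h) = target. With `skip > 0` the mean constraint covers
# only samples skip+1..n (used for recovery blocks, whose deceleration
# prefix is not part of the walk cell downstream). tau = 0 degenerates to a
# constant block at the target.
.hr_block <- function(h0, target, n, tau, skip = 0L) {
  if (n == 0L) return(numeric(0))
  if (tau <= 0) return(rep(target, n))
  r <- exp(-1 / tau)
  m <- n - skip
  cc <- r^skip * r * (1 - r^m) / (m * (1 - r))
  A <- (target - h0 * cc) / (1 - cc)
  A + (h0 - A) * r^seq_len(n)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-gait speed bands used for clipped draws; margins keep median-filtered
# speeds inside the printed bands.
.SPEED_BANDS <- list(walk = c(0.05, 1.60), trot = c(2.00, 4.10),
                     gallop = c(4.55, 12))

#' Generate one synthetic VST session
#'
#' 1 Hz telemetry: warm-up walk, then `n_races` blocks of approach trot,
#' gallop of sampled duration, a deceleration ramp crossing the transition
#' band, and a walking rest. Deterministic given `(seed, role,
#' subject_index)`.
#'
#' @param config A `vst_config`.
#' @param role `"PH"` or `"HH"`.
#' @param subject_index 1-based subject number within the role.
#' @param metadata Optional `subject_metadata`; defaults to the study-mean
#'   preset for the role.
#' @return An `exercise_session`.
#' @export
generate_session <- function(config, role, subject_index = 1L,
                             metadata = NULL) {
  stopifnot(inherits(config, "vst_config"))
  role <- match.arg(role, c("PH", "HH"))
  if (is.null(metadata)) {
    metadata <- study_mean_metadata(
      sprintf("%s%02d", role, subject_index), role)
  }
  set.seed(.substream(config$seed, role, subject_index))
  hr_t <- config$hr_targets[[role]] +
    stats::rnorm(3L, 0, config$hr_subject_sd)
  names(hr_t) <- names(config$hr_targets[[role]])
  v_t <- config$speed_targets[[role]]
  tau_up <- config$tau_rise
  tau_down <- unname(config$tau_recovery[[role]])

  speed_block <- function(gait, n) {
    band <- .SPEED_BANDS[[gait]]
    .clip(stats::rnorm(n, v_t[[gait]], config$speed_sd[[gait]]),
          band[1L], band[2L])
  }

  speed <- c(); hr <- c()
  h_last <- 60 # pre-exercise HR
  add_block <- function(gait, n, tau) {
    blk <- .hr_block(h_last, hr_t[[gait]], n, tau)
    hr <<- c(hr, blk)
    if (n > 0L) h_last <<- blk[n]
    speed <<- c(speed, speed_block(gait, n))
  }
  add_block("walk", config$warmup_s, tau_up)
  for (race in seq_len(config$n_races)) {
    add_block("trot", config$trot_s, tau_up)
    dur <- sample(config$race_duration_s[1L]:config$race_duration_s[2L], 1L)
    add_block("gallop", dur, tau_up)
    # deceleration ramp through the transition band; HR starts its recovery
    v_from <- speed[length(speed)]
    ramp <- v_from + (v_t[["walk"]] - v_from) *
      seq_len(config$decel_s) / (config$decel_s + 1)
    blk <- .hr_block(h_last, hr_t[["walk"]],
                     config$decel_s + config$rest_s, tau_down,
                     skip = config$decel_s)
    hr <- c(hr, blk)
    h_last <- blk[length(blk)]
    speed <- c(speed, ramp)
    speed <- c(speed, speed_block("walk", config$rest_s))
  }
  hr <- hr + stats::rnorm(length(hr), 0, config$hr_jitter_sd)
  hr <- .clip(hr, 22, 255)
  samples <- data.frame(
    t_s = seq_along(speed) - 1L,
    hr_bpm = round(hr, 2),
    speed_mps = round(speed, 3),
    cum_dist_m = round(cumsum(c(0, speed[-1L])), 3))
  exercise_session(metadata, samples)
}

#' Generate one synthetic lactate curve
#'
#' T0 is the role baseline; T1--T3 add per-race increments; T4/T5 decay
#' exponentially from the T3 value toward the role's late-recovery level
#' with the configured half-life (the decay target is the rest level, not
#' T0, because the published 240-min values sit below the resting values;
#' half-life 0 therefore returns the rest level at T4/T5). Between-subject
#' variation is multiplicative with coefficient of variation `cv`.
#' Deterministic given `(seed, role, subject_index)`.
#'
#' @inheritParams generate_session
#' @param subject_id Optional id; defaults to `"<role><index>"`.
#' @return A `lactate_curve`.
#' @export
generate_lactate <- function(config, role, subject_index = 1L,
                             subject_id = NULL) {
  stopifnot(inherits(config, "vst_config"))
  role <- match.arg(role, c("PH", "HH"))
  if (is.null(subject_id)) {
    subject_id <- sprintf("%s%02d", role, subject_index)
  }
  lc <- config$lactate[[role]]
  # offset the substream so lactate draws do not reuse the telemetry stream
  set.seed((.substream(config$seed, role, subject_index) + 104729L) %%
             2147483399L)
  scale <- if (lc$cv > 0) {
    exp(stats::rnorm(1L, -lc$cv^2 / 2, lc$cv))
  } else 1
  inc <- c(lc$increments, rep(0, max(0, 3 - length(lc$increments))))[1:3]
  t123 <- lc$baseline + cumsum(inc)
  peak <- t123[3L]
  decay <- function(minutes) {
    if (lc$half_life_min <= 0) return(lc$rest_level)
    lc$rest_level + (peak - lc$rest_level) *
      2^(-minutes / lc$half_life_min)
  }
  vals <- c(lc$baseline, t123, decay(30), decay(240)) * scale
  vals <- pmax(vals, 0.2)
  lactate_curve(subject_id, role,
                stats::setNames(vals, paste0("T", 0:5)))
}

#' Generate a full synthetic cohort
#'
#' `n_pairs` pull horses and `n_pairs` helper horses, each with a telemetry
#' session, a lactate curve and study-mean metadata. Reproducible per seed.
#'
#' @param config A `vst_config`.
#' @return List with elements `sessions`, `lactate` and `metadata`, each a
#'   named list keyed by subject id (PH first, then HH).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "vst_config"))
  ids <- c(sprintf("PH%02d", seq_len(config$n_pairs)),
           sprintf("HH%02d", seq_len(config$n_pairs)))
  roles <- rep(c("PH", "HH"), each = config$n_pairs)
  idx <- rep(seq_len(config$n_pairs), 2L)
  metadata <- Map(study_mean_metadata, ids, roles)
  sessions <- Map(function(r, i, m) generate_session(config, r, i, m),
                  roles, idx, metadata)
  curves <- Map(function(r, i, id) generate_lactate(config, r, i, id),
                roles, idx, ids)
  list(sessions = stats::setNames(sessions, ids),
       lactate = stats::setNames(curves, ids),
       metadata = stats::setNames(metadata, ids))
}
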
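# shared fixtures built in code

meta_ph <- function() subject_metadata("ph1", "PH", 428, 75, 10)
meta_hh <- function() subject_metadata("hh1", "HH", 428, 72.5, 10)

# minimal session from parallel vectors; cumulative distance integrates
# speed unless given explicitly
make_session <- function(hr, speed, metadata = meta_ph(), t = NULL,
                         dist = NULL) {
  n <- length(hr)
  stopifnot(length(speed) == n)
  if (is.null(t)) t <- seq_len(n) - 1L
  if (is.null(dist)) dist <- cumsum(c(0, speed[-n]))
  exercise_session(metadata,
                   data.frame(t_s = t, hr_bpm = hr, speed_mps = speed,
                              cum_dist_m = dist))
}

# small random-but-valid session for property loops
random_session <- function(n = 50L, seed = 1L) {
  set.seed(seed)
  speed <- pmax(0, stats::rnorm(n, 3, 2))
  make_session(hr = round(stats::runif(n, 40, 220), 2),
               speed = round(speed, 3))
}

labelled_cohort <- function(config) {
  coh <- generate_cohort(config)
  lapply(coh$sessions, function(s) {
    lab <- label_session(s)
    races <- detect_races(s, lab)
    list(session = s, labels = lab, races = races)
  })
}
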
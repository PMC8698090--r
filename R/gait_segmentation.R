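#' Gait speed bands
#'
#' The study's pace bands: walk below 1.67 m/s, trot 1.94--4.17 m/s
#' (inclusive), gallop above 4.44 m/s. The bands leave two unclassified
#' gaps, [1.67, 1.94) and (4.17, 4.44]; speeds there get the explicit label
#' `"transition"` rather than being silently attributed to a gait.
#'
#' @format Named numeric vector of the four band edges (m/s).
#' @export
GAIT_BANDS <- c(walk_max = 1.67, trot_min = 1.94, trot_max = 4.17,
                gallop_min = 4.44)

#' Classify a speed into a gait label
#'
#' Boundary semantics follow the printed inequalities literally: walk is
#' strict (`v < 1.67`), trot is inclusive (`1.94 <= v <= 4.17`), gallop is
#' strict (`v > 4.44`). Everything else is `"transition"`.
#'
#' @param speed_mps Non-negative finite speed(s) in m/s (vectorised).
#' @return Character vector of labels in
#'   `c("walk", "trot", "gallop", "transition")`.
#' @examples
#' classify_speed(c(1.0, 3.05, 6.95, 1.80))
#' @export
classify_speed <- function(speed_mps) {
  if (any(!is.finite(speed_mps)) || any(speed_mps < 0)) {
    stop("speed must be finite and non-negative", call. = FALSE)
  }
  out <- rep("transition", length(speed_mps))
  out[speed_mps < GAIT_BANDS[["walk_max"]]] <- "walk"
  out[speed_mps >= GAIT_BANDS[["trot_min"]] &
        speed_mps <= GAIT_BANDS[["trot_max"]]] <- "trot"
  out[speed_mps > GAIT_BANDS[["gallop_min"]]] <- "gallop"
  out
}

#' Label every sample of a session with a gait
#'
#' Labels are computed on a running median of the speed channel
#' (window 1 = no smoothing). The median filter suppresses single-sample
#' GPS jitter without moving bout edges by more than half the window.
#'
#' @param session An `exercise_session`.
#' @param smooth_window Odd positive integer window, default 3.
#' @return Character vector, one gait label per sample.
#' @export
label_session <- function(session, smooth_window = 3L) {
  stopifnot(inherits(session, "exercise_session"))
  if (length(smooth_window) != 1L || smooth_window < 1L ||
      smooth_window %% 2L == 0L) {
    stop("smooth_window must be an odd integer >= 1", call. = FALSE)
  }
  v <- session$samples$speed_mps
  if (smooth_window > 1L && length(v) >= smooth_window) {
    v <- stats::runmed(v, k = as.integer(smooth_window), endrule = "median")
  }
  classify_speed(as.numeric(v))
}

#' Extract maximal same-gait bouts
#'
#' Maximal runs of equal label become bouts with half-open `[start_s,
#' end_s)` spans that tile the session: every sample belongs to exactly one
#' bout, so sample counts, time and distance are conserved across bouts.
#' Bout means are arithmetic means over member samples; distance is the
#' difference of the cumulative-distance channel across the bout (the last
#' bout absorbs no following sample, so its distance runs to the final
#' sample).
#'
#' @param session An `exercise_session`.
#' @param labels Gait labels aligned to the samples, from
#'   [label_session()].
#' @return A data.frame with one row per bout: `label`, `start_s`, `end_s`,
#'   `n_samples`, `mean_hr_bpm`, `mean_speed_mps`, `distance_m`.
#' @export
extract_bouts <- function(session, labels) {
  stopifnot(inherits(session, "exercise_session"))
  s <- session$samples
  if (length(labels) != nrow(s)) {
    stop("labels (", length(labels), ") not aligned to samples (",
         nrow(s), ")", call. = FALSE)
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(r$lengths)
  last_t <- s$t_s[nrow(s)]
  bout <- function(i) {
    idx <- starts[i]:ends[i]
    # half-open span: end is the next bout's first timestamp (or last+1)
    end_s <- if (i < n) s$t_s[starts[i + 1L]] else last_t + 1L
    d_end <- if (i < n) s$cum_dist_m[starts[i + 1L]] else
      s$cum_dist_m[nrow(s)]
    data.frame(label = r$values[i], start_s = s$t_s[idx[1L]], end_s = end_s,
               n_samples = length(idx), mean_hr_bpm = mean(s$hr_bpm[idx]),
               mean_speed_mps = mean(s$speed_mps[idx]),
               distance_m = d_end - s$cum_dist_m[idx[1L]])
  }
  out <- do.call(rbind, lapply(seq_len(n), bout))
  rownames(out) <- NULL
  out
}

#' Detect the races of a vaquejada simulation test
#'
#' A race is a maximal gallop-dominated span containing at least
#' `min_gallop_s` consecutive gallop samples; gallop spans separated by less
#' than `min_rest_s` seconds of non-gallop are merged into one race. The VST
#' protocol is three races of 40--50 s with 5-min rests, so the defaults
#' (`min_gallop_s = 5`, `min_rest_s = 60`) sit far from both scales.
#'
#' @param session An `exercise_session`.
#' @param labels Gait labels aligned to the samples.
#' @param min_gallop_s Minimum consecutive gallop seconds to count as a
#'   race, default 5.
#' @param min_rest_s Gallop spans closer than this are merged, default 60.
#' @return A data.frame with one row per race: `index`, `start_s`, `end_s`
#'   (half-open), `distance_m`. Zero rows when no span qualifies.
#' @export
detect_races <- function(session, labels, min_gallop_s = 5L,
                         min_rest_s = 60L) {
  stopifnot(inherits(session, "exercise_session"),
            min_gallop_s >= 1L, min_rest_s >= 1L)
  s <- session$samples
  if (length(labels) != nrow(s)) {
    stop("labels not aligned to samples", call. = FALSE)
  }
  r <- rle(labels == "gallop")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  g <- which(r$values) # gallop runs (sample indices via starts/ends)
  if (length(g) == 0L) {
    return(data.frame(index = integer(0), start_s = numeric(0),
                      end_s = numeric(0), distance_m = numeric(0)))
  }
  run_start_t <- s$t_s[starts[g]]
  run_end_t <- s$t_s[ends[g]] + 1 # half-open
  # merge runs whose inter-run non-gallop gap is shorter than min_rest_s
  merged <- list()
  cur <- c(run_start_t[1L], run_end_t[1L])
  if (length(g) > 1L) {
    for (i in 2L:length(g)) {
      if (run_start_t[i] - cur[2L] < min_rest_s) {
        cur[2L] <- run_end_t[i]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(run_start_t[i], run_end_t[i])
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur
  # a merged span qualifies if it contains >= min_gallop_s consecutive
  # gallop samples
  keep <- vapply(merged, function(span) {
    inside <- s$t_s >= span[1L] & s$t_s < span[2L]
    rr <- rle(labels[inside] == "gallop")
    any(rr$values & rr$lengths >= min_gallop_s)
  }, logical(1L))
  merged <- merged[keep]
  if (length(merged) == 0L) {
    return(data.frame(index = integer(0), start_s = numeric(0),
                      end_s = numeric(0), distance_m = numeric(0)))
  }
  dist_of <- function(span) {
    idx <- which(s$t_s >= span[1L] & s$t_s < span[2L])
    s$cum_dist_m[max(idx)] - s$cum_dist_m[min(idx)]
  }
  data.frame(index = seq_along(merged),
             start_s = vapply(merged, `[`, numeric(1L), 1L),
             end_s = vapply(merged, `[`, numeric(1L), 2L),
             distance_m = vapply(merged, dist_of, numeric(1L)))
}

#' Export bouts or races as a BED-like table
#'
#' Writes a tab-separated table (`session_id`, `start_s`, `end_s`, `label`)
#' for quick inspection in standard interval tooling.
#'
#' @param session An `exercise_session`.
#' @param intervals A bouts or races data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intervals_bed <- function(session, intervals, path) {
  label <- if ("label" %in% names(intervals)) intervals$label else
    paste0("race_", intervals$index)
  out <- data.frame(session_id = session$metadata$subject_id,
                    start_s = intervals$start_s, end_s = intervals$end_s,
                    label = label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
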
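#' Timepoint schedule of the VST lactate protocol
#'
#' T0 at rest before exercise; T1--T3 immediately after races 1--3; T4 at
#' 30 min and T5 at 240 min of recovery. Nominal recovery minutes are `NA`
#' for the race timepoints, whose clock times depend on unrecorded race
#' timing.
#'
#' @format Data.frame with columns `timepoint` and `recovery_min`.
#' @export
LACTATE_SCHEDULE <- data.frame(
  timepoint = paste0("T", 0:5),
  recovery_min = c(NA, NA, NA, NA, 30, 240))

#' Construct a six-timepoint plasma lactate curve
#'
#' @param subject_id Character scalar.
#' @param role `"PH"` or `"HH"`.
#' @param values Positive finite concentrations in mmol/L, named by
#'   timepoint (or in schedule order T0..T5 when unnamed). At least 2
#'   points; labels must be unique, valid and in schedule order.
#' @return A `lactate_curve` object.
#' @examples
#' lactate_curve("ph_mean", "PH", c(2.2, 8.0, 9.5, 10.6, 4.1, 1.8))
#' @export
lactate_curve <- function(subject_id, role, values) {
  role <- match.arg(role, c("PH", "HH"))
  if (is.null(names(values))) {
    names(values) <- paste0("T", seq_along(values) - 1L)
  }
  labels <- names(values)
  if (!all(labels %in% LACTATE_SCHEDULE$timepoint) || anyDuplicated(labels)) {
    stop("timepoint labels must be unique members of T0..T5", call. = FALSE)
  }
  ord <- match(labels, LACTATE_SCHEDULE$timepoint)
  if (is.unsorted(ord, strictly = TRUE)) {
    stop("timepoints must be in schedule order T0 < ... < T5", call. = FALSE)
  }
  if (length(values) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("concentrations must be positive and finite", call. = FALSE)
  }
  structure(list(subject_id = subject_id, role = role,
                 values = as.numeric(values), labels = labels),
            class = "lactate_curve")
}

#' Summary statistics of a lactate curve
#'
#' @param curve A `lactate_curve` including T0.
#' @return List with `baseline` (the T0 value), `peak` (maximum
#'   concentration), `peak_timepoint` (label of the maximum, earliest on
#'   ties) and `delta` (`peak - baseline`), all mmol/L.
#' @export
curve_summary <- function(curve) {
  stopifnot(inherits(curve, "lactate_curve"))
  i0 <- match("T0", curve$labels)
  if (is.na(i0)) stop("curve has no T0 (resting) point", call. = FALSE)
  ipk <- which.max(curve$values) # earliest index on ties
  list(baseline = curve$values[i0], peak = curve$values[ipk],
       peak_timepoint = curve$labels[ipk],
       delta = curve$values[ipk] - curve$values[i0])
}

#' Timepoints exceeding a lactate threshold
#'
#' Strict exceedance, matching "above the anaerobic threshold" (the
#' conventional threshold is 4 mmol/L).
#'
#' @param curve A `lactate_curve`.
#' @param threshold Positive threshold in mmol/L, default 4.
#' @return Character vector of the labels whose concentration strictly
#'   exceeds `threshold` (possibly empty).
#' @export
threshold_exceedance <- function(curve, threshold = 4) {
  stopifnot(inherits(curve, "lactate_curve"), threshold > 0)
  curve$labels[curve$values > threshold]
}

#' Post-peak recovery assessment
#'
#' A subject is considered recovered at the earliest post-peak timepoint
#' whose concentration is at most its own baseline (T0) plus `tolerance`.
#' The study states recovery qualitatively; the default tolerance of
#' 0.5 mmol/L is this package's operational criterion.
#'
#' @param curve A `lactate_curve` including T0.
#' @param tolerance Non-negative tolerance in mmol/L, default 0.5.
#' @return The recovery timepoint label, or `NA_character_` if none
#'   qualifies.
#' @export
recovery_assessment <- function(curve, tolerance = 0.5) {
  stopifnot(inherits(curve, "lactate_curve"), tolerance >= 0)
  cs <- curve_summary(curve)
  ipk <- match(cs$peak_timepoint, curve$labels)
  post <- seq_along(curve$labels) > ipk
  ok <- post & curve$values <= cs$baseline + tolerance
  if (!any(ok)) NA_character_ else curve$labels[which(ok)[1L]]
}

#' Read lactate curves from long-format CSV
#'
#' Columns: `subject_id`, `role`, `timepoint`, `mmol_per_L`. One curve per
#' subject.
#'
#' @param path Path to the CSV file.
#' @return Named list of `lactate_curve` objects.
#' @export
read_lactate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "role", "timepoint", "mmol_per_L")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(match(d$timepoint, LACTATE_SCHEDULE$timepoint)), ]
    lactate_curve(d$subject_id[1L], d$role[1L],
                  stats::setNames(d$mmol_per_L, d$timepoint))
  })
  out[unique(df$subject_id)]
}

#' Write lactate curves to long-format CSV
#'
#' @param curves List of `lactate_curve` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lactate_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(subject_id = cv$subject_id, role = cv$role,
               timepoint = cv$labels, mmol_per_L = cv$values)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Published group-mean lactate curves
#'
#' The study's printed group means (mmol/L) per timepoint, shipped as a
#' plain-text fixture: pull horses (2.2, 8.0, 9.5, 10.6, 4.1, 1.8) and
#' helper horses (2.1, 5.6, 6.3, 6.7, 2.3, 2.3) at T0..T5.
#'
#' @return Named list of two `lactate_curve` objects, `PH` and `HH`.
#' @export
published_lactate_means <- function() {
  path <- system.file("extdata", "lactate_group_means.csv",
                      package = "vaquetics", mustWork = TRUE)
  curves <- read_lactate_csv(path)
  stats::setNames(curves, vapply(curves, `[[`, "", "role"))
}
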
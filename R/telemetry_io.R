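#' Subject metadata for an exercise session
#'
#' Bundles the identity, role and the three mass components (horse, rider,
#' tack) of one horse/rider pair. Roles follow vaquejada convention: `"PH"`
#' (pull horse, the pair member that topples the bull) or `"HH"` (helper
#' horse, the pair member that keeps the bull aligned).
#'
#' @param subject_id Character scalar identifying the subject.
#' @param role Either `"PH"` or `"HH"`.
#' @param horse_mass_kg,rider_mass_kg,tack_mass_kg Positive finite masses in
#'   kilograms.
#'
#' @return An object of class `subject_metadata` (a named list).
#' @examples
#' subject_metadata("h1", "PH", 428, 75, 10)
#' @export
subject_metadata <- function(subject_id, role, horse_mass_kg, rider_mass_kg,
                             tack_mass_kg) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            nzchar(subject_id))
  role <- match.arg(role, c("PH", "HH"))
  masses <- c(horse = horse_mass_kg, rider = rider_mass_kg,
              tack = tack_mass_kg)
  if (!all(is.finite(masses)) || any(masses <= 0)) {
    stop("all masses must be positive and finite", call. = FALSE)
  }
  structure(list(subject_id = subject_id, role = role,
                 horse_mass_kg = as.numeric(horse_mass_kg),
                 rider_mass_kg = as.numeric(rider_mass_kg),
                 tack_mass_kg = as.numeric(tack_mass_kg)),
            class = "subject_metadata")
}

#' Study-mean metadata presets
#'
#' The study reports only group means for masses: horses averaged 428 kg,
#' pull-horse riders 75 kg, helper-horse riders 72.5 kg, and tack about
#' 10 kg. Individual masses were not published, so these presets stand in
#' per role.
#'
#' @param subject_id Character scalar.
#' @param role `"PH"` or `"HH"`.
#' @return A `subject_metadata` object with the study-mean masses.
#' @export
study_mean_metadata <- function(subject_id, role) {
  role <- match.arg(role, c("PH", "HH"))
  rider <- if (role == "PH") 75 else 72.5
  subject_metadata(subject_id, role, 428, rider, 10)
}

#' Total carried mass
#'
#' Horse plus rider plus tack, the mass used to normalise cost of transport
#' and metabolic power.
#'
#' @param metadata A `subject_metadata` object.
#' @return Mass in kg.
#' @examples
#' total_carried_mass(subject_metadata("h1", "PH", 428, 75, 10)) # 513
#' @export
total_carried_mass <- function(metadata) {
  stopifnot(inherits(metadata, "subject_metadata"))
  metadata$horse_mass_kg + metadata$rider_mass_kg + metadata$tack_mass_kg
}

# Range limits for channel validation; values outside are physiologically or
# physically impossible for ridden horses at 1 Hz sampling.
.HR_RANGE <- c(20, 260)
.SPEED_RANGE <- c(0, 25)

#' Construct an exercise session
#'
#' A session is one horse's 1 Hz telemetry stream (time, heart rate, speed,
#' cumulative distance) plus its subject metadata. Validation enforces
#' strictly increasing whole-second timestamps, heart rate within
#' 20--260 beats/min, speed within 0--25 m/s, non-decreasing cumulative
#' distance, and at least two samples. Gaps (missing seconds) are permitted
#' but recorded in the `gaps` attribute.
#'
#' @param metadata A `subject_metadata` object.
#' @param samples A data.frame with columns `t_s`, `hr_bpm`, `speed_mps`,
#'   `cum_dist_m`.
#' @return An object of class `exercise_session`.
#' @export
exercise_session <- function(metadata, samples) {
  stopifnot(inherits(metadata, "subject_metadata"), is.data.frame(samples))
  required <- c("t_s", "hr_bpm", "speed_mps", "cum_dist_m")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[required]
  if (nrow(samples) < 2L) {
    stop("a session needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(samples)))) {
    bad <- which(!stats::complete.cases(samples) |
                   apply(!is.finite(as.matrix(samples)), 1L, any))[1L]
    stop("non-finite value at row ", bad, call. = FALSE)
  }
  t_s <- samples$t_s
  if (any(t_s != floor(t_s))) {
    warning("sub-second timestamps truncated to whole seconds",
            call. = FALSE)
    samples$t_s <- t_s <- floor(t_s)
  }
  dt <- diff(t_s)
  if (any(dt <= 0)) {
    stop("time not strictly increasing at row ", which(dt <= 0)[1L] + 1L,
         call. = FALSE)
  }
  hr <- samples$hr_bpm
  if (any(hr < .HR_RANGE[1L] | hr > .HR_RANGE[2L])) {
    bad <- which(hr < .HR_RANGE[1L] | hr > .HR_RANGE[2L])
    stop("hr_bpm out of range [20, 260] at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  v <- samples$speed_mps
  if (any(v < .SPEED_RANGE[1L] | v > .SPEED_RANGE[2L])) {
    bad <- which(v < .SPEED_RANGE[1L] | v > .SPEED_RANGE[2L])
    stop("speed_mps out of range [0, 25] at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  dd <- diff(samples$cum_dist_m)
  if (any(dd < 0)) {
    stop("cum_dist_m decreasing at row ", which(dd < 0)[1L] + 1L,
         call. = FALSE)
  }
  gaps <- t_s[which(dt > 1)] # last sample before each gap
  rownames(samples) <- NULL
  structure(list(metadata = metadata, samples = samples),
            gaps = gaps, class = "exercise_session")
}

#' @export
print.exercise_session <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<exercise_session> %s (%s): %d samples, %d s, %.0f m\n",
    x$metadata$subject_id, x$metadata$role, nrow(s),
    s$t_s[nrow(s)] - s$t_s[1L], s$cum_dist_m[nrow(s)] - s$cum_dist_m[1L]))
  invisible(x)
}

#' Read a session from the canonical CSV dialect
#'
#' The canonical dialect is plain CSV with header columns `t_s`, `hr_bpm`,
#' `speed_mps`, `cum_dist_m` and `.` as the decimal mark. Device exports
#' (FIT/TCX/...) are out of scope; convert to this dialect first.
#'
#' @param path Path to the CSV file.
#' @param metadata A `subject_metadata` object for the subject recorded in
#'   the file.
#' @return An `exercise_session`.
#' @seealso [write_session_csv()]
#' @export
read_session_csv <- function(path, metadata) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("t_s", "hr_bpm", "speed_mps", "cum_dist_m")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  exercise_session(metadata, df)
}

#' Write a session to the canonical CSV dialect
#'
#' Values are serialized with enough significant digits (15) that
#' `read_session_csv()` reproduces the session exactly.
#'
#' @param session An `exercise_session`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "exercise_session"))
  df <- session$samples
  out <- data.frame(
    t_s = format(df$t_s, trim = TRUE, scientific = FALSE),
    hr_bpm = format(df$hr_bpm, digits = 15, trim = TRUE, scientific = FALSE),
    speed_mps = format(df$speed_mps, digits = 15, trim = TRUE,
                       scientific = FALSE),
    cum_dist_m = format(df$cum_dist_m, digits = 15, trim = TRUE,
                        scientific = FALSE))
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read subject metadata from a key-value config file
#'
#' Plain `key = value` lines (or `key: value`); keys `subject_id`, `role`,
#' `horse_mass_kg`, `rider_mass_kg`, `tack_mass_kg`.
#'
#' @param path Path to the config file.
#' @return A `subject_metadata` object.
#' @export
read_metadata_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1L]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1L], collapse = ":")), "")
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("missing key: ", k, call. = FALSE)
    vals[i]
  }
  subject_metadata(get("subject_id"), get("role"),
                   as.numeric(get("horse_mass_kg")),
                   as.numeric(get("rider_mass_kg")),
                   as.numeric(get("tack_mass_kg")))
}

#' Write subject metadata to a key-value config file
#'
#' @param metadata A `subject_metadata` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metadata_file <- function(metadata, path) {
  stopifnot(inherits(metadata, "subject_metadata"))
  writeLines(c(
    paste0("subject_id = ", metadata$subject_id),
    paste0("role = ", metadata$role),
    paste0("horse_mass_kg = ", format(metadata$horse_mass_kg, digits = 15)),
    paste0("rider_mass_kg = ", format(metadata$rider_mass_kg, digits = 15)),
    paste0("tack_mass_kg = ", format(metadata$tack_mass_kg, digits = 15))),
    path)
  invisible(path)
}
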
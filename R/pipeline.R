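#' Run configuration for the VST pipeline
#'
#' Exactly one input mode is active: `"synthetic"` (a [vst_config()] drives
#' the generator) or `"csv_dir"` (a directory of `<id>_session.csv`,
#' `<id>_meta.txt` pairs plus one `lactate.csv`).
#'
#' @param input_mode `"synthetic"` or `"csv_dir"`.
#' @param out_dir Output directory for the report bundle.
#' @param generator A `vst_config` (synthetic mode).
#' @param csv_dir Input directory (csv_dir mode).
#' @param energetics An `energetics_config`.
#' @param smooth_window Odd gait-smoothing window, default 3.
#' @param min_gallop_s,min_rest_s Race-detection parameters.
#' @param alpha Significance level for group statistics, default 0.05.
#' @param lactate_tolerance Recovery tolerance in mmol/L, default 0.5.
#' @return A `run_config` object.
#' @export
run_config <- function(input_mode = c("synthetic", "csv_dir"),
                       out_dir,
                       generator = vst_preset(),
                       csv_dir = NULL,
                       energetics = energetics_config(),
                       smooth_window = 3L, min_gallop_s = 5L,
                       min_rest_s = 60L, alpha = 0.05,
                       lactate_tolerance = 0.5) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "csv_dir" && (is.null(csv_dir) || !dir.exists(csv_dir))) {
    stop("csv_dir mode needs an existing input directory", call. = FALSE)
  }
  structure(list(input_mode = input_mode, out_dir = out_dir,
                 generator = generator, csv_dir = csv_dir,
                 energetics = energetics, smooth_window = smooth_window,
                 min_gallop_s = min_gallop_s, min_rest_s = min_rest_s,
                 alpha = alpha, lactate_tolerance = lactate_tolerance),
            class = "run_config")
}

.load_csv_cohort <- function(dir) {
  meta_files <- list.files(dir, pattern = "_meta\\.txt$", full.names = TRUE)
  if (length(meta_files) == 0L) {
    stop("no <id>_meta.txt files found in ", dir, call. = FALSE)
  }
  ids <- sub("_meta\\.txt$", "", basename(meta_files))
  metadata <- lapply(meta_files, read_metadata_file)
  names(metadata) <- ids
  sessions <- lapply(ids, function(id) {
    p <- file.path(dir, paste0(id, "_session.csv"))
    if (!file.exists(p)) stop("missing session file for subject ", id,
                              call. = FALSE)
    read_session_csv(p, metadata[[id]])
  })
  names(sessions) <- ids
  lac_path <- file.path(dir, "lactate.csv")
  lactate <- if (file.exists(lac_path)) read_lactate_csv(lac_path) else list()
  list(sessions = sessions, lactate = lactate, metadata = metadata)
}

#' Run the full VST analysis
#'
#' Reads or generates a cohort, labels gaits, detects races, computes
#' energetics summaries, lactate summaries and PH-vs-HH statistics, and
#' writes a report bundle to `config$out_dir`:
#' \itemize{
#'   \item `energetics_tidy.csv` -- one row per subject x race x gait cell
#'     (plus totals);
#'   \item `energetics_table.csv` -- lettered mean (SD) comparison per
#'     variable x race x gait row;
#'   \item `lactate_summary.csv` -- per subject: baseline, peak, peak
#'     timepoint, delta, threshold exceedances, recovery timepoint;
#'   \item `lactate_table.csv` -- lettered PH-vs-HH comparison per
#'     timepoint;
#'   \item `stats_tidy.csv` -- per-condition group means/SDs, F, p,
#'     letters;
#'   \item `races.csv`, `warnings.txt`, `manifest.json` (config hash,
#'     package version, COT mode).
#' }
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the cohort, per-subject summaries, the
#'   statistics tables and the manifest.
#' @export
run_vst_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warn_log <- character(0)
  note <- function(...) warn_log <<- c(warn_log, sprintf(...))

  cohort <- if (config$input_mode == "synthetic") {
    generate_cohort(config$generator)
  } else {
    .load_csv_cohort(config$csv_dir)
  }
  if (length(cohort$sessions) == 0L) {
    stop("stage load: empty cohort", call. = FALSE)
  }

  ids <- names(cohort$sessions)
  summaries <- list(); race_rows <- list()
  for (id in ids) {
    sess <- cohort$sessions[[id]]
    labels <- withCallingHandlers(
      label_session(sess, config$smooth_window),
      warning = function(w) {
        note("subject %s: %s", id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tf <- mean(labels == "transition")
    if (tf > 0.10) note("subject %s: transition fraction %.1f%%",
                        id, 100 * tf)
    races <- detect_races(sess, labels, config$min_gallop_s,
                          config$min_rest_s)
    if (nrow(races) == 0L) {
      stop("stage segmentation, subject ", id, ": no races detected",
           call. = FALSE)
    }
    summ <- withCallingHandlers(
      summarize_session(sess, labels, races, config$energetics),
      warning = function(w) {
        note("subject %s: %s", id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    summaries[[id]] <- summ
    race_rows[[id]] <- cbind(subject_id = id, races)
  }
  tidy <- do.call(rbind, summaries)
  rownames(tidy) <- NULL

  # group statistics per variable x (race x gait) condition
  stats_long <- list()
  for (var in c("mean_hr_bpm", "mean_speed_mps", "ee_J_per_kg_min",
                "cot_scaled", "pmet_scaled")) {
    d <- data.frame(group = tidy$role,
                    condition = sprintf("%s | race %s | %s", var,
                                        tidy$race, tidy$gait),
                    value = tidy[[var]])
    d <- d[!is.na(d$value), ]
    stats_long[[var]] <- d
  }
  all_long <- do.call(rbind, stats_long)
  have_groups <- length(unique(all_long$group)) >= 2L &&
    min(table(unique(tidy[c("subject_id", "role")])$role)) >= 2L
  energ_tab <- if (have_groups) summary_table(all_long, alpha = config$alpha)
    else NULL

  # lactate summaries
  lac_sum <- NULL; lac_tab <- NULL
  if (length(cohort$lactate) > 0L) {
    lac_sum <- do.call(rbind, lapply(cohort$lactate, function(cv) {
      cs <- curve_summary(cv)
      data.frame(subject_id = cv$subject_id, role = cv$role,
                 baseline = cs$baseline, peak = cs$peak,
                 peak_timepoint = cs$peak_timepoint, delta = cs$delta,
                 above_4mmol = paste(threshold_exceedance(cv, 4),
                                     collapse = ";"),
                 recovered_at = recovery_assessment(
                   cv, config$lactate_tolerance))
    }))
    rownames(lac_sum) <- NULL
    lac_long <- do.call(rbind, lapply(cohort$lactate, function(cv) {
      data.frame(group = cv$role, condition = cv$labels, value = cv$values)
    }))
    roles_n <- table(vapply(cohort$lactate, `[[`, "", "role"))
    if (length(roles_n) >= 2L && min(roles_n) >= 2L) {
      lac_tab <- summary_table(lac_long, alpha = config$alpha, digits = 1)
    }
  }

  manifest <- list(
    package = "vaquetics",
    version = as.character(utils::packageVersion("vaquetics")),
    input_mode = config$input_mode,
    preset = attr(config$generator, "preset"),
    seed = if (config$input_mode == "synthetic") config$generator$seed,
    cot_mode = config$energetics$cot_mode,
    alpha = config$alpha,
    n_subjects = length(ids),
    config_hash = .config_hash(config))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.csv(tidy, out("energetics_tidy.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, race_rows), out("races.csv"),
                   row.names = FALSE)
  if (!is.null(energ_tab)) {
    utils::write.csv(energ_tab$table, out("energetics_table.csv"),
                     row.names = FALSE)
    utils::write.csv(energ_tab$stats, out("stats_tidy.csv"),
                     row.names = FALSE)
  }
  if (!is.null(lac_sum)) {
    utils::write.csv(lac_sum, out("lactate_summary.csv"), row.names = FALSE)
  }
  if (!is.null(lac_tab)) {
    utils::write.csv(lac_tab$table, out("lactate_table.csv"),
                     row.names = FALSE)
  }
  writeLines(if (length(warn_log)) warn_log else "none", out("warnings.txt"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(cohort = cohort, tidy = tidy, energetics_table = energ_tab,
                 lactate_summary = lac_sum, lactate_table = lac_tab,
                 manifest = manifest, warnings = warn_log))
}

# Stable hash of the run configuration (drops the output path so reruns
# into a different directory hash identically).
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  dump <- paste(utils::capture.output(utils::str(cfg, digits.d = 15)),
                collapse = "\n")
  # FNV-1a over the serialized text; cheap and dependency-free
  h <- 2166136261
  for (b in utf8ToInt(dump)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort's CSVs), `analyze`
#' (run the pipeline on a CSV directory), `report` (synthetic end-to-end
#' run). Flags: `--seed`, `--out`, `--in`, `--preset`, `--pairs`,
#' `--cot-mode`, `--alpha`. Installed as `inst/cli/vst.R`; run with
#' `Rscript $(Rscript -e 'cat(system.file("cli/vst.R", package="vaquetics"))') report --seed 1 --out out/`.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status, invisibly (0 on success).
#' @export
vst_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L ||
      !args[1L] %in% c("simulate", "analyze", "report")) {
    message("usage: vst.R <simulate|analyze|report> [options]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "vst_out"),
    optparse::make_option("--in", type = "character",
                          default = NULL, dest = "input"),
    optparse::make_option("--preset", type = "character",
                          default = "coelho2021"),
    optparse::make_option("--pairs", type = "integer", default = 4L),
    optparse::make_option("--cot-mode", type = "character",
                          default = "dimensional", dest = "cot_mode"),
    optparse::make_option("--alpha", type = "double", default = 0.05)))
  opt <- optparse::parse_args(parser, args = args[-1L])
  gen <- vst_preset(opt$preset, n_pairs = opt$pairs, seed = opt$seed)
  ecfg <- energetics_config(cot_mode = opt$cot_mode)
  if (cmd == "simulate") {
    cohort <- generate_cohort(gen)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    for (id in names(cohort$sessions)) {
      write_session_csv(cohort$sessions[[id]],
                        file.path(opt$out, paste0(id, "_session.csv")))
      write_metadata_file(cohort$metadata[[id]],
                          file.path(opt$out, paste0(id, "_meta.txt")))
    }
    write_lactate_csv(cohort$lactate, file.path(opt$out, "lactate.csv"))
    jsonlite::write_json(list(preset = attr(gen, "preset"),
                              seed = gen$seed, n_pairs = gen$n_pairs),
                         file.path(opt$out, "manifest.json"),
                         auto_unbox = TRUE)
    message("wrote ", 2L * gen$n_pairs, " subjects to ", opt$out)
  } else if (cmd == "analyze") {
    if (is.null(opt$input)) {
      message("analyze needs --in <dir>")
      return(invisible(1L))
    }
    cfg <- run_config("csv_dir", out_dir = opt$out, csv_dir = opt$input,
                      energetics = ecfg, alpha = opt$alpha)
    run_vst_analysis(cfg)
    message("report bundle written to ", opt$out)
  } else {
    cfg <- run_config("synthetic", out_dir = opt$out, generator = gen,
                      energetics = ecfg, alpha = opt$alpha)
    run_vst_analysis(cfg)
    message("report bundle written to ", opt$out)
  }
  invisible(0L)
}
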
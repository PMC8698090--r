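test_that("generation is deterministic per seed and varies across seeds", {
  cfg <- vst_preset(n_pairs = 1L, seed = 6L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$sessions$PH01$samples, b$sessions$PH01$samples)
  expect_identical(a$lactate$HH01$values, b$lactate$HH01$values)
  c2 <- generate_cohort(vst_preset(n_pairs = 1L, seed = 7L))
  expect_false(identical(a$sessions$PH01$samples$hr_bpm,
                         c2$sessions$PH01$samples$hr_bpm))
})

test_that("cohorts have the protocol structure", {
  coh <- generate_cohort(vst_preset(seed = 1L))
  expect_length(coh$sessions, 8L)
  expect_length(coh$lactate, 8L)
  roles <- vapply(coh$metadata, `[[`, "", "role")
  expect_equal(as.vector(table(roles)[c("PH", "HH")]), c(4L, 4L))
  expect_equal(total_carried_mass(coh$metadata$PH01), 513)
  expect_equal(total_carried_mass(coh$metadata$HH01), 510.5)
  # gallop bouts last 40-50 s (plus ramp/smoothing slack)
  for (id in c("PH02", "HH03")) {
    s <- coh$sessions[[id]]
    labs <- label_session(s)
    b <- extract_bouts(s, labs)
    g <- b[b$label == "gallop" & b$n_samples >= 5, ]
    expect_equal(nrow(g), 3L)
    expect_true(all(g$n_samples >= 40 & g$n_samples <= 53))
  }
})

test_that("noise-free limit reproduces targets exactly", {
  # decel_s = 1 keeps the single ramp sample out of the gallop band, so
  # every gallop-cell sample sits exactly at the target in this limit
  cfg <- vst_preset(n_pairs = 1L, seed = 1L, hr_subject_sd = 0,
                    hr_jitter_sd = 0, tau_rise = 0,
                    tau_recovery = c(PH = 0, HH = 0), decel_s = 1L)
  s <- generate_session(cfg, "PH", 1L)
  labs <- label_session(s)
  races <- detect_races(s, labs)
  summ <- summarize_session(s, labs, races)
  gallop <- summ[summ$gait == "gallop", ]
  expect_equal(gallop$mean_hr_bpm,
               rep(cfg$hr_targets$PH[["gallop"]], nrow(gallop)))
  walk <- summ[summ$gait == "walk", ]
  expect_equal(walk$mean_hr_bpm,
               rep(cfg$hr_targets$PH[["walk"]], nrow(walk)))
})

test_that("pipeline recovers generator targets at default noise", {
  cfg <- vst_preset(seed = 1L) # n_pairs = 4
  coh <- labelled_cohort(cfg)
  cells <- do.call(rbind, lapply(coh, function(x) {
    as.data.frame(summarize_session(x$session, x$labels, x$races))
  }))
  cells <- cells[cells$gait %in% c("walk", "gallop") &
                   cells$n_samples >= 30, ]
  agg <- aggregate(cbind(mean_hr_bpm, mean_speed_mps) ~ role + gait,
                   data = cells, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    role <- agg$role[i]; gait <- agg$gait[i]
    expect_lt(abs(agg$mean_hr_bpm[i] - cfg$hr_targets[[role]][[gait]]), 2)
    expect_lt(abs(agg$mean_speed_mps[i] - cfg$speed_targets[[role]][[gait]]),
              0.2)
  }
})

test_that("lactate kinetics reproduce the published means when noise-free", {
  cfg <- vst_preset(n_pairs = 1L, seed = 1L)
  cfg$lactate$PH$cv <- 0
  cfg$lactate$HH$cv <- 0
  ph <- generate_lactate(cfg, "PH", 1L)
  expect_equal(ph$values, c(2.2, 8.0, 9.5, 10.6, 4.1, 1.8),
               tolerance = 0.10)
  hh <- generate_lactate(cfg, "HH", 1L)
  expect_equal(hh$values, c(2.1, 5.6, 6.3, 6.7, 2.3, 2.3),
               tolerance = 0.10)

  # zero increments: flat at baseline through T3
  cfg0 <- cfg
  cfg0$lactate$PH$increments <- c(0, 0, 0)
  cfg0$lactate$PH$rest_level <- cfg0$lactate$PH$baseline
  flat <- generate_lactate(cfg0, "PH", 1L)
  expect_equal(unique(round(flat$values, 9)),
               cfg0$lactate$PH$baseline)

  # instant clearance: half-life 0 returns the rest level at T4/T5
  cfgi <- cfg
  cfgi$lactate$HH$half_life_min <- 0
  inst <- generate_lactate(cfgi, "HH", 1L)
  expect_equal(unname(inst$values[5:6]),
               rep(cfgi$lactate$HH$rest_level, 2))
})

test_that("built-in role contrasts mirror the published directionality", {
  cfg <- vst_preset(seed = 9L)
  expect_gt(cfg$hr_targets$PH[["gallop"]], cfg$hr_targets$HH[["gallop"]])
  expect_gt(cfg$hr_targets$HH[["trot"]], cfg$hr_targets$PH[["trot"]])
  # and the generated data carry them
  coh <- labelled_cohort(cfg)
  cells <- do.call(rbind, lapply(coh, function(x) {
    as.data.frame(summarize_session(x$session, x$labels, x$races))
  }))
  per_subj <- aggregate(mean_hr_bpm ~ subject_id + role + gait,
                        data = cells[cells$gait != "total", ], FUN = mean)
  g <- per_subj[per_subj$gait == "gallop", ]
  t <- per_subj[per_subj$gait == "trot", ]
  expect_gt(mean(g$mean_hr_bpm[g$role == "PH"]),
            mean(g$mean_hr_bpm[g$role == "HH"]))
  expect_gt(mean(t$mean_hr_bpm[t$role == "HH"]),
            mean(t$mean_hr_bpm[t$role == "PH"]))
})

test_that("invalid generator configs are rejected", {
  expect_error(vst_config(n_pairs = 0L))
  expect_error(vst_config(race_duration_s = c(50L, 40L)))
  expect_error(vst_config(hr_jitter_sd = -1))
  bad_lac <- list(PH = list(baseline = -2, increments = c(1, 1, 1),
                            rest_level = 1.8, half_life_min = 15, cv = 0.1),
                  HH = list(baseline = 2.1, increments = c(1, 1, 1),
                            rest_level = 2.3, half_life_min = 5, cv = 0.1))
  expect_error(vst_config(lactate = bad_lac), "lactate")
})
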
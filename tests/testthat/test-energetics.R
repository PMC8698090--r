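test_that("energy expenditure follows the power law", {
  expect_equal(energy_expenditure(0), 0)
  expect_equal(energy_expenditure(1), 0.0566)
  # independent evaluation of 0.0566 * 100^1.9955 via exp/log
  expect_equal(energy_expenditure(100), 0.0566 * exp(1.9955 * log(100)),
               tolerance = 1e-12)
  expect_equal(energy_expenditure(100), 554.4, tolerance = 1e-3)
  # strict monotonicity and linearity in the coefficient
  hr <- seq(0, 240, by = 0.5)
  ee <- energy_expenditure(hr)
  expect_true(all(diff(ee) > 0))
  cfg2 <- energetics_config(ee_coeff = 0.1132)
  expect_equal(energy_expenditure(hr, cfg2), 2 * ee, tolerance = 1e-12)
  expect_error(energy_expenditure(-5), "non-negative")
})

test_that("cost of transport matches hand arithmetic in both modes", {
  cfg <- energetics_config()
  expect_equal(cost_of_transport(35, 500, distance_m = 100,
                                 duration_s = 60, config = cfg), 0)
  # dimensional: (185-35) * (25/60) / (500*150) * 1e3
  expect_equal(cost_of_transport(185, 500, distance_m = 150,
                                 duration_s = 25, config = cfg),
               150 * (25 / 60) / (500 * 150) * 1e3, tolerance = 1e-12)
  expect_equal(cost_of_transport(185, 500, distance_m = 150,
                                 duration_s = 25, config = cfg),
               0.833, tolerance = 1e-3)
  # paper_numeric: (189.98-35) / (6.5*513) * 1e3, same order as the
  # published gallop values
  cfgp <- energetics_config(cot_mode = "paper_numeric")
  expect_equal(cost_of_transport(189.98, 513, mean_speed_mps = 6.5,
                                 config = cfgp),
               154.98 / (6.5 * 513) * 1e3, tolerance = 1e-12)
  expect_equal(cost_of_transport(189.98, 513, mean_speed_mps = 6.5,
                                 config = cfgp), 46.5, tolerance = 0.05)
  expect_warning(
    out <- cost_of_transport(30, 500, distance_m = 100, duration_s = 60,
                             config = cfg), "clamped")
  expect_equal(out, 0)
  expect_error(cost_of_transport(120, -1, distance_m = 100,
                                 duration_s = 60, config = cfg), "mass")
  expect_error(cost_of_transport(120, 500, config = cfg), "distance")
  expect_error(cost_of_transport(120, 500, mean_speed_mps = 0,
                                 config = cfgp), "speed")
})

test_that("metabolic power is linear above baseline and mass-inverse", {
  expect_equal(metabolic_power(35, 500), 0)
  expect_equal(metabolic_power(135, 500), 200)
  expect_equal(metabolic_power(111.27, 510.5), 149.4, tolerance = 1e-3)
  # linear in (HR - baseline), inverse in mass
  expect_equal(metabolic_power(235, 500), 2 * metabolic_power(135, 500))
  expect_equal(metabolic_power(135, 1000), metabolic_power(135, 500) / 2)
  expect_error(metabolic_power(135, 0), "mass")
  # scale_factor = 1 returns the literal formula
  cfg1 <- energetics_config(scale_factor = 1)
  expect_equal(metabolic_power(135, 500, cfg1), 100 / 500)
})

test_that("summarize_session reduces constant streams exactly", {
  s <- make_session(hr = rep(100, 60), speed = rep(6, 60))
  labs <- label_session(s)
  races <- detect_races(s, labs)
  summ <- summarize_session(s, labs, races)
  cell <- summ[summ$gait == "gallop", ]
  expect_equal(cell$ee_J_per_kg_min, energy_expenditure(100))
  expect_equal(cell$mean_hr_bpm, 100)
  expect_equal(cell$mean_speed_mps, 6)
  # ee_on = "mean_hr" agrees on constant streams
  summ2 <- summarize_session(s, labs, races,
                             energetics_config(ee_on = "mean_hr"))
  expect_equal(summ2$ee_J_per_kg_min, summ$ee_J_per_kg_min)
  expect_error(summarize_session(s, labs, races[0, ]), "race")
})

test_that("session totals conserve sample-weighted cell means", {
  sess <- generate_session(vst_preset(seed = 4L), "PH", 2L)
  labs <- label_session(sess)
  races <- detect_races(sess, labs)
  summ <- summarize_session(sess, labs, races)
  cells <- summ[summ$gait != "total", ]
  tot <- summ[summ$gait == "total", ]
  expect_equal(sum(cells$n_samples), tot$n_samples)
  expect_equal(sum(cells$n_samples * cells$mean_hr_bpm) / tot$n_samples,
               tot$mean_hr_bpm)
  expect_equal(sum(cells$n_samples * cells$ee_J_per_kg_min) / tot$n_samples,
               tot$ee_J_per_kg_min)
  expect_equal(sum(cells$distance_m), tot$distance_m)
  # transition samples excluded but accounted
  expect_equal(tot$n_samples + attr(summ, "transition_s"),
               nrow(sess$samples))
})

test_that("hr zone fractions partition the session", {
  s <- make_session(hr = rep(100, 10), speed = rep(1, 10))
  expect_equal(unname(hr_zone_fractions(s, 150)), c(1, 0))
  s <- make_session(hr = c(rep(140, 50), rep(160, 50)), speed = rep(1, 100))
  expect_equal(unname(hr_zone_fractions(s, 150)), c(0.5, 0.5))
  f <- hr_zone_fractions(s, c(100, 150, 200))
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_error(hr_zone_fractions(s, c(150, 100)), "increasing")
})

test_that("role-specific recovery builds the below-150-bpm contrast in", {
  coh <- generate_cohort(vst_preset(seed = 2L))
  f <- vapply(coh$sessions, function(s) hr_zone_fractions(s, 150)[1L],
              numeric(1L))
  roles <- vapply(coh$metadata, `[[`, "", "role")
  expect_lt(mean(f[roles == "PH"]), mean(f[roles == "HH"]))
})
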
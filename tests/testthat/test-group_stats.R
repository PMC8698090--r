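test_that("ks normality screen separates normal from uniform samples", {
  set.seed(7)
  p_norm <- replicate(100, ks_normality(stats::rnorm(1000))$p.value)
  expect_gte(mean(p_norm > 0.05), 0.95)
  p_unif <- replicate(100,
                      ks_normality(stats::runif(1000) * 100)$p.value)
  expect_gte(mean(p_unif < 0.05), 0.95)
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2)), "at least 3")
  # lilliefors correction still rejects scaled uniforms
  set.seed(8)
  expect_lt(ks_normality(stats::runif(500) * 100, lilliefors = TRUE)$p.value,
            0.05)
})

test_that("rm_anova matches closed forms and the aov oracle", {
  # deterministic condition effect with zero within-subject error
  panel <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  out <- rm_anova(panel)
  expect_equal(out$p, 0)
  # all subjects identical across conditions -> F = 0, p = 1
  flat <- matrix(5, nrow = 4, ncol = 3)
  outf <- rm_anova(flat)
  expect_equal(outf$F, 0)
  expect_equal(outf$p, 1)

  # two conditions: F equals the paired t statistic squared
  set.seed(11)
  x <- matrix(stats::rnorm(16), nrow = 8, ncol = 2)
  t2 <- stats::t.test(x[, 1], x[, 2], paired = TRUE)$statistic^2
  expect_equal(rm_anova(x)$F, unname(t2), tolerance = 1e-9)

  # general case: agree with the aov() repeated-measures decomposition
  set.seed(12)
  y <- matrix(stats::rnorm(24, mean = rep(c(0, 1, 0.5, 2), each = 6)),
              nrow = 6)
  d <- data.frame(val = as.vector(y),
                  subj = factor(rep(1:6, times = 4)),
                  cond = factor(rep(1:4, each = 6)))
  fit <- stats::aov(val ~ cond + Error(subj / cond), data = d)
  ref <- summary(fit)[["Error: subj:cond"]][[1]]
  mine <- rm_anova(y)
  expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-9)

  # invariance under shift and scale
  expect_equal(rm_anova(y + 100)$F, mine$F, tolerance = 1e-9)
  expect_equal(rm_anova(y * 3.7)$F, mine$F, tolerance = 1e-9)

  y2 <- y; y2[2, 3] <- NA
  rownames(y2) <- paste0("s", 1:6)
  expect_error(rm_anova(y2), "s2")
  expect_error(rm_anova(y[1, , drop = FALSE]), ">= 2 subjects")
})

test_that("tukey pairwise comparisons behave like Tukey HSD", {
  set.seed(3)
  a <- stats::rnorm(8); b <- a # identical groups
  out <- tukey_pairwise(c(a, b), rep(c("A", "B"), each = 8))
  expect_gt(out$p_adj, 0.99)
  expect_false(out$significant)

  # 10 pooled SDs apart: detected
  g1 <- stats::rnorm(8, 0, 1); g2 <- stats::rnorm(8, 10, 1)
  out <- tukey_pairwise(c(g1, g2), rep(c("A", "B"), each = 8))
  expect_true(out$significant)

  # three groups: adjusted p >= unadjusted pairwise p
  g3 <- stats::rnorm(8, 0.5, 1)
  vals <- c(g1, g2, g3)
  grp <- rep(c("A", "B", "C"), each = 8)
  out <- tukey_pairwise(vals, grp)
  for (i in seq_len(nrow(out))) {
    x <- vals[grp == out$group1[i]]
    y <- vals[grp == out$group2[i]]
    p_raw <- stats::t.test(x, y, var.equal = TRUE)$p.value
    expect_gte(out$p_adj[i] + 1e-9, p_raw)
  }
  # symmetric in group order
  out_r <- tukey_pairwise(rev(vals), rev(grp))
  key <- function(d) {
    d$pair <- paste(pmin(d$group1, d$group2), pmax(d$group1, d$group2))
    d[order(d$pair), c("pair", "p_adj")]
  }
  expect_equal(key(out)$p_adj, key(out_r)$p_adj, tolerance = 1e-9)
  expect_error(tukey_pairwise(c(1, 2, 3), c("A", "A", "B")), "n < 2")
})

test_that("rm_anova type-I error is calibrated at alpha 0.05", {
  set.seed(2024)
  n_rep <- 2000L
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    panel <- matrix(stats::rnorm(48), nrow = 8, ncol = 6)
    rej[i] <- rm_anova(panel)$p <= 0.05
  }
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("summary tables format means, SDs and letters", {
  set.seed(21)
  d <- data.frame(group = rep(c("HH", "PH"), each = 8),
                  condition = "lactate T3",
                  value = c(stats::rnorm(8, 6.7, 0.5),
                            stats::rnorm(8, 10.6, 0.5)))
  out <- summary_table(d, digits = 1)
  expect_equal(out$table$condition, "lactate T3")
  # separated groups get distinct letters, higher mean first letter
  expect_match(out$table$PH, "\\(±[0-9.]+\\) a$")
  expect_match(out$table$HH, "\\(±[0-9.]+\\) b$")
  expect_true(all(out$stats$p <= 1, out$stats$p >= 0))

  # formatting: mean 10.6, sd 2.6 in 1-decimal mode
  d2 <- data.frame(group = "PH", condition = "x",
                   value = c(8, 10.6, 13.2))
  out2 <- summary_table(d2, digits = 1)
  expect_equal(out2$stats$mean, 10.6)
  expect_match(out2$table$PH, "^10.6 \\(±2.6\\)")

  # indistinguishable groups carry no letters
  set.seed(5)
  d3 <- data.frame(group = rep(c("HH", "PH"), each = 8), condition = "y",
                   value = stats::rnorm(16))
  out3 <- summary_table(d3)
  expect_false(grepl("[ab]$", out3$table$PH))
})
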
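#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD. Using estimated parameters makes the test
#' approximate (anti-conservative); a Lilliefors-style correction is
#' available via `lilliefors = TRUE`, which calibrates the p value by
#' parametric simulation.
#'
#' @param values Numeric sample, n >= 3, non-degenerate.
#' @param lilliefors Simulate the null distribution of the statistic under
#'   parameter estimation (999 replicates) instead of using the asymptotic
#'   KS p value. Default `FALSE`, matching common applied usage.
#' @return List with `statistic` and `p.value`.
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s))
  if (lilliefors) {
    n <- length(values)
    stat0 <- vapply(seq_len(999L), function(i) {
      x <- stats::rnorm(n)
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))$statistic
    }, numeric(1L))
    p <- (1 + sum(stat0 >= kt$statistic)) / 1000
    return(list(statistic = unname(kt$statistic), p.value = p))
  }
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Repeated-measures one-way ANOVA
#'
#' Within-subject one-way ANOVA for a condition effect on a complete
#' subjects-by-conditions matrix: the F ratio is the condition mean square
#' over the subject-by-condition interaction mean square, with
#' `(k - 1)` and `(k - 1)(n - 1)` degrees of freedom.
#'
#' @param panel Numeric matrix, rows = subjects, columns = conditions.
#'   Must be complete (no `NA`); n >= 2 subjects, k >= 2 conditions.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
rm_anova <- function(panel) {
  panel <- as.matrix(panel)
  if (!is.numeric(panel)) stop("panel must be numeric", call. = FALSE)
  if (anyNA(panel)) {
    bad <- which(apply(is.na(panel), 1L, any))
    nm <- if (is.null(rownames(panel))) bad else rownames(panel)[bad]
    stop("missing cells for subject(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(panel); k <- ncol(panel)
  if (n < 2L || k < 2L) {
    stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  }
  grand <- mean(panel)
  cond_means <- colMeans(panel)
  subj_means <- rowMeans(panel)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- panel - outer(subj_means, cond_means, `+`) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  if (ms_err == 0) {
    # all subjects identical profile shifts: no within-subject variability
    f <- if (ms_cond == 0) 0 else Inf
  } else {
    f <- ms_cond / ms_err
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, p = p, df1 = df1, df2 = df2)
}

#' Pairwise Tukey HSD comparisons
#'
#' All pairwise mean differences between groups with studentized-range
#' adjusted p values, flagged at `alpha`.
#'
#' @param values Numeric measurements.
#' @param groups Group labels aligned to `values`; >= 2 groups, each with
#'   n >= 2.
#' @param alpha Significance level, default 0.05.
#' @return Data.frame with columns `group1`, `group2`, `diff`
#'   (`mean(group1) - mean(group2)`), `p_adj`, `significant`.
#' @export
tukey_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("group(s) with n < 2: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group1 = vapply(pairs, `[`, "", 1L),
    group2 = vapply(pairs, `[`, "", 2L),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"]) <= alpha)
  rownames(out) <- NULL
  out
}

#' One-way between-group ANOVA at a fixed condition
#'
#' The study's between-role contrast: a one-way ANOVA across the role
#' groups of one variable at one condition (equivalent to a two-sample
#' pooled-variance t test when there are two roles).
#'
#' @inheritParams tukey_pairwise
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  fit <- stats::anova(stats::lm(values ~ groups))
  list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L],
       df1 = fit$Df[1L], df2 = fit$Df[2L])
}

# Assign compact letters from the insignificance graph: groups sharing a
# letter are NOT significantly different. Greedy clique cover ordered by
# decreasing mean; exact for <= 2 groups and adequate for the small group
# counts used here.
.compact_letters <- function(group_means, pairs) {
  groups <- names(sort(group_means, decreasing = TRUE))
  ng <- length(groups)
  insig <- matrix(TRUE, ng, ng, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    if (isTRUE(pairs$significant[i])) {
      g1 <- pairs$group1[i]; g2 <- pairs$group2[i]
      insig[g1, g2] <- insig[g2, g1] <- FALSE
    }
  }
  if (all(insig)) return(stats::setNames(rep("", ng), groups))
  letters_out <- stats::setNames(rep("", ng), groups)
  next_letter <- 1L
  covered <- matrix(FALSE, ng, ng, dimnames = list(groups, groups))
  for (g in groups) {
    for (h in groups) {
      if (g != h && insig[g, h] && !covered[g, h]) {
        # grow a clique containing g,h
        clique <- c(g, h)
        for (k in setdiff(groups, clique)) {
          if (all(insig[k, clique])) clique <- c(clique, k)
        }
        lt <- letters[next_letter]; next_letter <- next_letter + 1L
        for (m in clique) letters_out[m] <- paste0(letters_out[m], lt)
        covered[clique, clique] <- TRUE
      }
    }
    if (!any(insig[g, setdiff(groups, g)])) {
      lt <- letters[next_letter]; next_letter <- next_letter + 1L
      letters_out[g] <- paste0(letters_out[g], lt)
    }
  }
  letters_out
}

#' Lettered mean (+/- SD) comparison table
#'
#' Builds the publication-style wide table: one row per condition, one
#' "mean (+/-SD)" column per group, with superscript-style letters marking
#' Tukey-significant differences within a row (groups sharing a letter do
#' not differ; rows with no significant contrast carry no letters), plus
#' the between-group ANOVA p value.
#'
#' @param data Long data.frame with columns `group`, `condition`, `value`.
#' @param alpha Significance level, default 0.05.
#' @param digits Decimal places for means and SDs, default 2.
#' @return List with `table` (wide character data.frame) and `stats` (tidy
#'   per-condition data.frame: condition, per-group mean/sd, F, p, letters).
#' @export
summary_table <- function(data, alpha = 0.05, digits = 2) {
  stopifnot(all(c("group", "condition", "value") %in% names(data)))
  conds <- unique(data$condition)
  grps <- sort(unique(as.character(data$group)))
  fmt <- function(m, s) {
    sprintf(paste0("%.", digits, "f (±%.", digits, "f)"), m, s)
  }
  tidy <- list(); wide <- list()
  for (cd in conds) {
    d <- data[data$condition == cd, ]
    means <- tapply(d$value, d$group, mean)[grps]
    sds <- tapply(d$value, d$group, stats::sd)[grps]
    sizes <- table(factor(d$group, levels = grps))
    can_test <- length(grps) >= 2L && all(sizes >= 2L) &&
      stats::var(d$value) > 0
    if (can_test) {
      aov1 <- oneway_anova(d$value, d$group)
      pairs <- tukey_pairwise(d$value, d$group, alpha = alpha)
      lets <- .compact_letters(means, pairs)
    } else {
      aov1 <- list(F = NA_real_, p = NA_real_)
      lets <- stats::setNames(rep("", length(grps)), grps)
    }
    cells <- paste0(fmt(means, sds),
                    ifelse(nzchar(lets[grps]),
                           paste0(" ", lets[grps]), ""))
    wide[[length(wide) + 1L]] <- c(condition = cd,
                                   stats::setNames(cells, grps),
                                   p = ifelse(is.na(aov1$p), "",
                                              sprintf("%.3f", aov1$p)))
    tidy[[length(tidy) + 1L]] <- data.frame(
      condition = cd, group = grps, mean = as.numeric(means),
      sd = as.numeric(sds), F = aov1$F, p = aov1$p,
      letters = unname(lets[grps]))
  }
  wide_df <- as.data.frame(do.call(rbind, wide), stringsAsFactors = FALSE)
  rownames(wide_df) <- NULL
  list(table = wide_df, stats = do.call(rbind, tidy))
}
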
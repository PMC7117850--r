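# split-plot sums of squares computed from first principles on a balanced
# table: an oracle independent of aov()
split_plot_oracle <- function(d) {
  d$weekf <- factor(d$week)
  a_means <- tapply(d$value, d$animal, mean)
  g_of_a <- tapply(as.character(d$group), d$animal, function(x) x[1])
  nt <- nlevels(d$weekf)
  grand <- mean(d$value)
  g_means <- tapply(d$value, d$group, mean)
  t_means <- tapply(d$value, d$weekf, mean)
  n_per_g <- table(g_of_a)

  ss_group <- nt * sum(n_per_g * (g_means[names(n_per_g)] - grand)^2)
  ss_anim <- nt * sum((a_means - g_means[g_of_a])^2)
  ss_time <- length(a_means) * sum((t_means - grand)^2)
  cell <- tapply(d$value, list(d$group, d$weekf), mean)
  ncell <- rep(n_per_g[rownames(cell)], nt)
  ss_cells <- sum(ncell * (as.vector(cell) - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_time
  ss_tot <- sum((d$value - grand)^2)
  ss_err <- ss_tot - ss_cells - ss_anim

  ng <- length(g_means)
  df_g <- ng - 1; df_a <- length(a_means) - ng
  df_t <- nt - 1; df_i <- df_g * df_t; df_e <- df_a * df_t
  data.frame(
    effect = c("group", "week", "group:week"),
    F = c((ss_group / df_g) / (ss_anim / df_a),
          (ss_time / df_t) / (ss_err / df_e),
          (ss_inter / df_i) / (ss_err / df_e)),
    p = c(pf((ss_group / df_g) / (ss_anim / df_a), df_g, df_a, lower.tail = FALSE),
          pf((ss_time / df_t) / (ss_err / df_e), df_t, df_e, lower.tail = FALSE),
          pf((ss_inter / df_i) / (ss_err / df_e), df_i, df_e, lower.tail = FALSE)))
}

test_that("the repeated-measures ANOVA matches a first-principles decomposition", {
  d <- generate_study(study_design(
    groups = data.frame(name = c("a", "b", "c"), n_animals = c(4, 4, 4)),
    timepoints = c(1, 2, 3),
    effects = data.frame(group = "c", week = 3, parameter = "BV_TV",
                         effect_sd = 1.5),
    seed = 77))
  got <- rm_anova(d)
  want <- split_plot_oracle(d)
  expect_equal(got$F, want$F, tolerance = 1e-6)
  expect_equal(got$p, want$p, tolerance = 1e-6)
})

test_that("degenerate and invalid inputs are handled", {
  d <- generate_study(study_design(seed = 1))
  d$value <- 1  # all identical
  om <- rm_anova(d)
  expect_equal(om$F, c(0, 0, 0))
  expect_equal(om$p, c(1, 1, 1))
  one_week <- generate_study(study_design(timepoints = 11))
  expect_error(rm_anova(one_week), "2 groups")
})

test_that("animals missing a timepoint are dropped listwise from the ANOVA", {
  d <- generate_study(study_design(seed = 5))
  drop <- d$animal == "control_01" & d$week == 52
  got <- rm_anova(d[!drop, ])
  manual <- rm_anova(d[d$animal != "control_01", ])
  expect_equal(got$F, manual$F)
})

test_that("Tukey pairwise comparisons behave across separations", {
  base <- expand.grid(animal = 1:6, group = c("a", "b"))
  base$value <- 10; base$week <- 1
  base$animal <- paste0(base$group, base$animal)
  d0 <- base; d0$value <- rep(c(5, 5), each = 6) + rep(c(0.1, -0.1), 6)
  p_same <- tukey_pairs(d0, 1)
  expect_gt(p_same$p_adj, 0.9)

  set.seed(8)
  d1 <- base
  d1$value <- rnorm(12) + ifelse(d1$group == "b", 10, 0)  # 10 pooled SDs
  expect_lt(tukey_pairs(d1, 1)$p_adj, 1e-6)

  # multiplicity: with >2 groups the adjusted p is at least the t-test p
  d2 <- generate_study(study_design(seed = 13))
  tp <- tukey_pairs(d2[d2$week == 11, ], 11)
  x <- d2$value[d2$week == 11 & d2$group == "control"]
  y <- d2$value[d2$week == 11 & d2$group == "sham"]
  pt2 <- t.test(x, y, var.equal = TRUE)$p.value
  row <- grepl("control", tp$pair) & grepl("sham", tp$pair)
  expect_gte(tp$p_adj[row], pt2)
})

test_that("group summaries report n, mean and SD with flags for singletons", {
  d <- data.frame(animal = c("a1", "a2", "a3", "b1"),
                  group = c("a", "a", "a", "b"),
                  week = 1, parameter = "x",
                  value = c(1, 2, 3, 7))
  s <- summarize_groups(d)
  expect_equal(s$mean[s$group == "a"], 2)
  expect_equal(s$sd[s$group == "a"], 1)
  expect_true(is.na(s$sd[s$group == "b"]))
  const <- d; const$value <- 4
  expect_equal(summarize_groups(const)$sd[1], 0)
})

test_that("power rises with effect size and matches the studentised-range tail", {
  gr <- data.frame(name = c("control", "sham", "low", "medium", "high"),
                   n_animals = rep(10, 5))
  detect <- function(effect_sd, reps = 60) {
    hits <- 0
    for (r in seq_len(reps)) {
      ef <- data.frame(group = "high", week = 52, parameter = "BV_TV",
                       effect_sd = effect_sd)
      d <- generate_study(study_design(groups = gr, effects = ef,
                                       seed = 3000 + r))
      tp <- tukey_pairs(d[d$week == 52, ], 52)
      hits <- hits + (tp$p_adj[grepl("high", tp$pair) &
                               grepl("sham", tp$pair)] < 0.05)
    }
    hits / reps
  }
  p0 <- detect(0); p2 <- detect(2); p4 <- detect(4)
  expect_lte(p0, 0.15)
  expect_gt(p2, p0)
  expect_gte(p4, p2)
  expect_gt(p4, 0.95)
  # analytic check at +2 SD: noncentral t against the Tukey critical value
  q_crit <- qtukey(0.95, 5, 45) / sqrt(2)
  ncp <- 2 / sqrt(2 / 10)
  p_analytic <- 1 - pt(q_crit, 45, ncp)
  expect_lt(abs(p2 - p_analytic), 3 * sqrt(p_analytic * (1 - p_analytic) / 60))
})

test_that("compare_groups flags the loaded group against sham", {
  ef <- data.frame(group = "high", week = c(22, 34, 52), parameter = "BV_TV",
                   effect_sd = 4)
  d <- generate_study(study_design(
    groups = data.frame(name = c("control", "sham", "high"),
                        n_animals = c(6, 6, 10)),
    effects = ef, seed = 21))
  res <- compare_groups(d, sham = "sham")
  vs <- res$BV_TV$vs_sham
  expect_true(all(vs$significant[vs$group == "high" & vs$week >= 22]))
  expect_false(any(vs$significant[vs$group == "control" & vs$week <= 14]))
  expect_true(all(vs$p_adj >= 0 & vs$p_adj <= 1))
})
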
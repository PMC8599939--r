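test_that("Fisher z is atanh with clamping, and averaging back-transforms", {
  expect_equal(fisher_z(0), 0)
  r <- c(-0.8, -0.2, 0, 0.3, 0.9)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(0.54), atanh(0.54))
  expect_warning(z1 <- fisher_z(1), "clamping")
  expect_true(is.finite(z1))
  m <- mean_fisher_z(c(0.5, 0.6))
  expect_equal(m$mean_r, tanh(mean(atanh(c(0.5, 0.6)))))
})

test_that("paired t-test matches closed forms and the printed df convention", {
  a <- rnorm(10)
  res <- paired_t(a, a)
  expect_equal(unname(res), c(0, 9, 1))
  # 38 paired units give df = 37
  set.seed(33)
  x <- rnorm(38); y <- x + rnorm(38, 0.5)
  expect_equal(paired_t(y, x)[["df"]], 37)
  # hand-computable triple: differences (1, 2, 3) -> t = 2 * sqrt(3)
  res3 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res3[["t"]], 2 * sqrt(3), tolerance = 1e-12)
  # agrees with stats::t.test
  tt <- t.test(y, x, paired = TRUE)
  expect_equal(paired_t(y, x)[["t"]], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(paired_t(y, x)[["p"]], tt$p.value, tolerance = 1e-12)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
})

test_that("one-sample t-test matches closed forms and flags degenerate input", {
  v <- c(-2, -1, 1, 2)
  expect_equal(one_sample_t(v)[["t"]], 0)
  set.seed(34)
  x <- rnorm(15, 0.4)
  tt <- t.test(x, mu = 0)
  expect_equal(one_sample_t(x)[["t"]], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(one_sample_t(x)[["p"]], tt$p.value, tolerance = 1e-12)
  expect_error(one_sample_t(c(1, 1, 1)), "zero-variance")
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(rep(0.02, 4)), rep(0.08, 4))
})

test_that("mixed ANOVA matches the brute-force sums-of-squares oracle", {
  # 2 groups x 3 within levels, 2 units per group: 12 rows
  set.seed(35)
  df <- expand.grid(unit = paste0("u", 1:4), stim = c("s1", "s2", "s3"))
  df$group <- ifelse(df$unit %in% c("u1", "u2"), "HC", "PD")
  df$y <- round(rnorm(12, sd = 2) + as.numeric(df$stim == "s2"), 3)
  tab <- mixed_anova(df, dv = "y", between = "group", within = "stim",
                     unit = "unit")
  o <- brute_mixed_anova_2xw(df, "y", "group", "stim", "unit")
  g <- function(eff) tab[tab$effect == eff, ]
  expect_equal(g("group")$ss, o$between$ss, tolerance = 1e-10)
  expect_equal(g("group")$ss_error, o$between$ss_err, tolerance = 1e-10)
  expect_equal(g("stim")$ss, o$within$ss, tolerance = 1e-10)
  expect_equal(g("stim")$ss_error, o$within$ss_err, tolerance = 1e-10)
  expect_equal(g("group:stim")$ss, o$interaction$ss, tolerance = 1e-10)
  expect_equal(g("group")$df1, o$between$df1)
  expect_equal(g("group")$df2, o$between$df2)
  expect_equal(g("stim")$df1, o$within$df1)
  expect_equal(g("stim")$df2, o$within$df2)
  # F from SS/df ratio
  expect_equal(g("stim")$F,
               (o$within$ss / o$within$df1) / (o$within$ss_err / o$within$df2),
               tolerance = 1e-10)
  # SS additivity for the balanced design
  expect_equal(sum(o$ss_parts), o$ss_total, tolerance = 1e-10)
  # partial eta^2 recomputable from the table's own SS entries
  pes <- partial_eta_squared(tab)
  expect_equal(unname(pes["stim"]),
               g("stim")$ss / (g("stim")$ss + g("stim")$ss_error))
  expect_true(all(pes >= 0 & pes <= 1))
})

test_that("mixed ANOVA validates balance and sphericity bookkeeping", {
  df <- expand.grid(unit = paste0("u", 1:6), stim = c("a", "b", "c"))
  df$group <- rep(c("HC", "PD"), each = 3)[match(df$unit, paste0("u", 1:6))]
  set.seed(36)
  df$y <- rnorm(nrow(df))
  tab <- mixed_anova(df, "y", "group", "stim", "unit")
  # GG epsilon defined for the 3-level within factor, in (1/(k-1), 1]
  eps <- tab$gg_eps[tab$effect == "stim"]
  expect_true(eps > 0.5 && eps <= 1 + 1e-12)
  expect_false(is.na(tab$p_gg[tab$effect == "stim"]))
  expect_true(is.na(tab$gg_eps[tab$effect == "group"]))
  # missing cell errors with the offending pair named
  expect_error(mixed_anova(df[-1, ], "y", "group", "stim", "unit"),
               "unbalanced")
  # a 2-level within factor is exactly spherical: epsilon 1
  df2 <- df[df$stim != "c", ]
  tab2 <- mixed_anova(df2, "y", "group", "stim", "unit")
  expect_equal(tab2$gg_eps[tab2$effect == "stim"], 1)
})

test_that("two within factors produce the full effect decomposition", {
  set.seed(37)
  df <- expand.grid(unit = paste0("u", 1:6), stim = c("a", "b", "c"),
                    band = c("x", "y"))
  df$group <- rep(c("HC", "PD"), each = 3)[match(df$unit, paste0("u", 1:6))]
  df$y <- rnorm(nrow(df))
  tab <- mixed_anova(df, "y", "group", within = c("stim", "band"), "unit")
  expect_setequal(tab$effect,
                  c("group", "stim", "group:stim", "band", "group:band",
                    "stim:band", "group:stim:band"))
  expect_true(all(tab$F >= 0))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})

test_that("behavior summary tabulates cells and detects planted stimulus effects", {
  # subject-level power: conditions generated at ~+10% MV for GVS
  hits <- vapply(1:10, function(k) {
    sch <- generate_trial_schedule(cohort_config(seed = 400 + k))
    bs <- behavior_summary(data.frame(subject_id = sch$subject_id,
                                      group = sch$group,
                                      condition = sch$condition,
                                      mv = sch$mv_true))
    bs$anova$p[bs$anova$effect == "condition"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  sch <- generate_trial_schedule(cohort_config(seed = 55))
  bs <- behavior_summary(data.frame(subject_id = sch$subject_id,
                                    group = sch$group, condition = sch$condition,
                                    mv = sch$mv_true))
  expect_equal(nrow(bs$table), 6)  # 2 groups x 3 conditions
  expect_equal(sum(bs$table$n_subjects), 3 * 38)
  # sham mean MV near 14e-4, GVS means higher
  sham <- bs$table$mean_mv[bs$table$condition == "sham"]
  gvs1 <- bs$table$mean_mv[bs$table$condition == "gvs1"]
  expect_true(all(gvs1 > sham))
  expect_error(behavior_summary(data.frame(
    subject_id = c("a", "a", "b", "b"), group = c("HC", "HC", "PD", "PD"),
    condition = c("sham", "gvs1", "sham", "gvs1"), mv = c(1, 2, 3, 4) * 1e-3)),
    "at least 2 subjects")
})

test_that("null behavioral data give uniform condition p-values", {
  set.seed(38)
  ps <- vapply(1:60, function(k) {
    df <- expand.grid(subject_id = paste0("s", 1:8),
                      condition = c("a", "b", "c"))
    df$group <- rep(c("HC", "PD"), each = 4)[match(df$subject_id,
                                                   paste0("s", 1:8))]
    df$mv <- rnorm(nrow(df))
    tab <- mixed_anova(df, "mv", "group", "condition", "subject_id")
    tab$p[tab$effect == "condition"]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
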
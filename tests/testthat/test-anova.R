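test_that("split-plot SS match the closed form on a pure-offset toy", {
  # 2 genotypes x 2 treatments x 2 reps, shade = CK + 4 everywhere:
  # treatment SS = n_per_group * offset^2 / 2 = 4 * 16 / 2 = 32, all else 0
  rows <- expand.grid(genotype_id = c("G1", "G2"), treatment = c("CK", "shade"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  rows$origin <- NA_character_; rows$location <- "HLJ"; rows$trait <- "PH"
  rows$value <- 10 + 4 * (rows$treatment == "shade")
  panel <- shadetol:::validate_panel(rows)
  f <- fit_split_plot(panel, "PH", "HLJ")
  tab <- f$anova_table
  expect_equal(tab$sum_sq[tab$effect == "cropping_system"], 32)
  expect_equal(sum(tab$sum_sq[tab$effect != "cropping_system"]), 0)
  expect_equal(sum(tab$df), nrow(rows) - 1)
  expect_equal(unname(f$stratum_means), c(10, 14))
})

test_that("split-plot fit matches the aov error-strata oracle", {
  cfg <- hlj_config(12, seed = 31)
  panel <- simulate_panel(cfg)
  f <- fit_split_plot(panel, "SYP", "HLJ")
  tab <- f$anova_table

  d <- as.data.frame(panel)
  d <- d[d$trait == "SYP" & d$location == "HLJ", ]
  d$R <- factor(d$replicate); d$C <- factor(d$treatment); d$G <- factor(d$genotype_id)
  oracle <- summary(stats::aov(value ~ C * G + Error(R / C), data = d))
  wp <- oracle[["Error: R:C"]][[1]]
  sp <- oracle[["Error: Within"]][[1]]

  get <- function(eff, col) tab[[col]][tab$effect == eff]
  expect_equal(get("cropping_system", "sum_sq"), wp["C", "Sum Sq"], tolerance = 1e-8)
  expect_equal(get("wholeplot_error", "sum_sq"), wp["Residuals", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(get("cropping_system", "statistic"), wp["C", "F value"],
               tolerance = 1e-8)
  expect_equal(get("cropping_system", "p_value"), wp["C", "Pr(>F)"],
               tolerance = 1e-8)
  expect_equal(get("genotype", "sum_sq"), sp["G", "Sum Sq"], tolerance = 1e-8)
  expect_equal(get("system_x_genotype", "sum_sq"), sp["C:G", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(get("genotype", "statistic"), sp["G", "F value"], tolerance = 1e-8)
  expect_equal(get("system_x_genotype", "p_value"), sp["C:G", "Pr(>F)"],
               tolerance = 1e-8)
  expect_equal(get("subplot_error", "sum_sq"), sp["Residuals", "Sum Sq"],
               tolerance = 1e-8)
})

test_that("split-plot SS are additive and df sum to N - 1", {
  for (s in 1:5) {
    panel <- simulate_panel(hlj_config(10, seed = 200 + s))
    f <- fit_split_plot(panel, "PNP", "HLJ")
    tab <- f$anova_table
    d <- panel$value[panel$trait == "PNP" & panel$location == "HLJ"]
    total_ss <- sum((d - mean(d))^2)
    expect_equal(sum(tab$sum_sq), total_ss, tolerance = 1e-8 * total_ss)
    expect_equal(sum(tab$df), length(d) - 1)
  }
})

test_that("split-plot fit requires both treatments and flags imbalance", {
  panel <- simulate_panel(hlj_config(6, seed = 1))
  ck_only <- panel[panel$treatment == "CK", ]
  expect_error(fit_split_plot(ck_only, "PH", "HLJ"), "both treatments")
  expect_error(fit_split_plot(panel, "PH", "NM"), "no rows")
  unbal <- panel[-which(panel$trait == "PH" & panel$genotype_id == "G0001" &
                          panel$replicate == 1L & panel$treatment == "CK")[1], ]
  expect_warning(fit_split_plot(unbal, "PH", "HLJ"), "unbalanced")
})

test_that("two-way ANOVA is symmetric in location labels and validates input", {
  m <- aggregate_to_means(simulate_panel(default_sim_config(25, seed = 9)))
  a1 <- two_way_anova(m, "SYP")
  swapped <- m
  swapped$location <- ifelse(m$location == "HLJ", "NM", "HLJ")
  a2 <- two_way_anova(swapped, "SYP")
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-10)
  expect_equal(a1$effect,
               c("location", "treatment", "location_x_treatment", "residuals"))
  expect_error(two_way_anova(m[m$location == "HLJ", ], "SYP"), "both locations")
})

test_that("two-way ANOVA stays null-calibrated when only location acts", {
  # location effect only: treatment and interaction should be ns almost always
  ns_t <- 0; ns_i <- 0; n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    cfg <- default_sim_config(40, seed = 300 + s)
    tm <- cfg$trait_means
    for (l in c("HLJ", "NM")) {
      ck <- tm$mean[tm$location == l & tm$treatment == "CK" & tm$trait == "PH"]
      tm$mean[tm$location == l & tm$trait == "PH"] <- ck
    }
    cfg$trait_means <- tm
    a <- two_way_anova(aggregate_to_means(simulate_panel(cfg)), "PH")
    ns_t <- ns_t + (a$p_value[a$effect == "treatment"] >= 0.05)
    ns_i <- ns_i + (a$p_value[a$effect == "location_x_treatment"] >= 0.05)
  }
  expect_gte(ns_t / n_seeds, 0.9)
  expect_gte(ns_i / n_seeds, 0.9)
})

test_that("percent change reproduces the ratio arithmetic", {
  expect_equal(round(percent_change(118.60, 127.49), 1), 7.5)
  expect_equal(round(percent_change(70.17, 64.40), 1), -8.2)
  expect_equal(percent_change(3.7, 3.7), 0)
  expect_true(is.na(percent_change(0, 1)))
  # identity with the uncapped tolerance index
  set.seed(5)
  for (i in 1:100) {
    a <- runif(1, 0.05, 80); b <- runif(1, 0, 160)
    expect_equal(percent_change(a, b), (trait_ti(a, b, cap = Inf) - 1) * 100,
                 tolerance = 1e-12)
  }
})

test_that("Cohen's d uses the pooled SD and is antisymmetric", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(cohens_d(y, x), 1 / sp)
  expect_equal(cohens_d(x, x), 0)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_true(is.na(cohens_d(rep(1, 4), rep(0, 4))))
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  # Hedges correction shrinks toward zero
  expect_lt(abs(cohens_d(y, x, hedges = TRUE)), abs(cohens_d(y, x)))
})

test_that("assumption checks delegate to Shapiro-Wilk and Levene", {
  set.seed(11)
  g <- rep(c("a", "b"), each = 50)
  x <- rnorm(100)
  chk <- assumption_checks(x, g)
  expect_gt(chk$shapiro_p, 0.001)
  expect_gt(chk$levene_p, 0.001)
  # identical groups: zero Levene statistic by convention
  chk0 <- assumption_checks(rep(c(1, 1, 1, 2, 2, 2), 2), rep(c("a", "b"), 6))
  expect_equal(chk0$levene_statistic, 0)
  expect_warning(assumption_checks(c(1, 2), c("a", "b")), "skipped")
})

test_that("normality p-values are uniform under the null and reject skew", {
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    assumption_checks(rnorm(100), rep(c("a", "b"), 50))$shapiro_p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  rejected <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    suppressWarnings(
      assumption_checks(exp(rnorm(100)), rep(c("a", "b"), 50))$shapiro_p) < 0.05
  }, TRUE)
  expect_gte(mean(rejected), 0.95)
})

test_that("shade effect table signs and scope behave", {
  m <- aggregate_to_means(simulate_panel(default_sim_config(30, seed = 13)))
  ef <- shade_effect_table(m, location = "HLJ")
  expect_equal(ef$trait, trait_names())
  expect_true(all(sign(ef$percent_change) ==
                    sign(ef$shade_mean - ef$ck_mean)))
  expect_true(all(sign(ef$cohens_d) == sign(ef$shade_mean - ef$ck_mean)))
  pooled <- shade_effect_table(m)
  expect_equal(unique(pooled$scope), "pooled")
})
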
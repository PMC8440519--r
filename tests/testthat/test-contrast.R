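test_that("positivity gate matches a one-sided t-test oracle", {
  set.seed(1)
  z <- matrix(rnorm(30 * 5, mean = c(5, 0, -2, 0.5, 3)), 30, 5, byrow = TRUE)
  g <- positivity_gate(z, alpha = 0.01)
  oracle <- apply(z, 2, function(x)
    t.test(x, alternative = "greater")$p.value)
  expect_equal(g$p, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(g$retained[1])
  expect_false(g$retained[3])
  # Bonferroni arithmetic: raw p ~ 2e-4 among 100 voxels is rejected
  set.seed(42)
  x <- rnorm(20)
  x <- (x - mean(x)) / sd(x)
  target <- x + 0.85  # tuned offset: one-sided p near 2e-4
  p_raw <- t.test(target, alternative = "greater")$p.value
  expect_gt(p_raw * 100, 0.01)   # would fail the corrected gate
  pad <- matrix(rnorm(20 * 99), 20, 99)
  g2 <- positivity_gate(cbind(target, pad), alpha = 0.01)
  expect_false(g2$retained[1])
  # zero-variance voxels: sign of the mean decides
  zv <- cbind(rep(2, 10), rep(-1, 10), rnorm(10))
  g3 <- positivity_gate(zv)
  expect_equal(g3$p[1:2], c(0, 1))
})

test_that("omnibus ANOVA matches oneway.test and gates correctly", {
  set.seed(2)
  groups <- rep(c("HC", "SZ", "ASD"), each = 40)
  v <- matrix(rnorm(120 * 6), 120, 6)
  v[, 1] <- v[, 1] + rep(c(0, 1, 2), each = 40)
  an <- omnibus_anova(v, groups, alpha = 0.05, correction = "none")
  oracle <- apply(v, 2, function(y)
    stats::oneway.test(y ~ groups, var.equal = TRUE)$p.value)
  expect_equal(an$p, unname(oracle), tolerance = 1e-10)
  expect_true(an$pass[1])
  # identical groups: F ~ 0, p ~ 1
  const <- matrix(rep(rnorm(40), 3), 120, 1)
  an0 <- omnibus_anova(const, groups, 0.05, "none")
  expect_gt(an0$p[1], 0.99)
  expect_false(an0$pass[1])
  expect_error(omnibus_anova(v[1:41, , drop = FALSE],
                             c(rep("HC", 40), "SZ"), 0.05, "none"),
               "at least 2")
})

test_that("ANOVA type-I rate is near nominal on null features", {
  set.seed(3)
  groups <- rep(c("HC", "SZ", "ASD"), each = 50)
  v <- matrix(rnorm(150 * 1000), 150, 1000)
  rate <- mean(omnibus_anova(v, groups, 0.05, "none")$pass)
  bound <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), bound)
})

test_that("pairwise t-tests follow the pooled-t oracle and sign convention", {
  set.seed(4)
  n <- 30
  v <- matrix(rnorm(3 * n * 4), 3 * n, 4)
  groups <- rep(c("HC", "SZ", "ASD"), each = n)
  v[groups == "HC", 1] <- v[groups == "HC", 1] + 1  # HC larger
  cr <- pairwise_ttests(v, groups)
  oracle <- t.test(v[groups == "HC", 1], v[groups == "SZ", 1],
                   var.equal = TRUE)
  expect_equal(cr$t_hc_sz[1], unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(cr$p_hc_sz[1], oracle$p.value, tolerance = 1e-12)
  expect_gt(cr$t_hc_sz[1], 0)  # HC higher => positive T
  # antisymmetry: swapping the pair negates T, preserves p
  sw <- col_ttest_pooled(v[groups == "SZ", , drop = FALSE],
                         v[groups == "HC", , drop = FALSE])
  expect_equal(sw$t, -col_ttest_pooled(v[groups == "HC", , drop = FALSE],
                                       v[groups == "SZ", , drop = FALSE])$t)
  # identical samples: T = 0, p = 1
  same <- rbind(v[1:n, ], v[1:n, ], v[1:n, ])
  cr2 <- pairwise_ttests(same, groups)
  expect_equal(cr2$t_hc_sz, rep(0, 4))
  expect_equal(cr2$p_hc_sz, rep(1, 4))
})

test_that("multiple-comparison corrections follow their definitions", {
  # m = 1: both reduce to p < alpha
  expect_true(correct_multiple(0.04, "BFN", 0.05))
  expect_true(correct_multiple(0.04, "FDR", 0.05))
  expect_false(correct_multiple(0.06, "BFN", 0.05))
  # hand-worked BH step-up at 0.05
  expect_equal(correct_multiple(c(0.001, 0.02, 0.03, 0.9), "FDR", 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  # Bonferroni is strict
  expect_false(correct_multiple(rep(0.0025, 4), "BFN", 0.01)[1])  # 0.01 !< 0.01
  expect_true(all(!correct_multiple(rep(1, 5), "BFN", 0.05)))
  expect_true(all(!correct_multiple(rep(1, 5), "FDR", 0.05)))
  expect_error(correct_multiple(numeric(0), "BFN", 0.05), "empty")
})

test_that("categorization matches the exhaustive sign truth table", {
  signs <- c(-1, 0, 1)
  grid <- expand.grid(ths = signs, tha = signs)
  cr <- data.frame(t_hc_sz = grid$ths * 2.1, t_hc_asd = grid$tha * 1.3,
                   t_sz_asd = 0)
  got <- categorize_changes(cr, rep(TRUE, nrow(cr)))
  # independent enumeration of the definition
  oracle <- mapply(function(a, b) {
    if (a > 0 && b > 0) "COMMON_DECREASE"
    else if (a < 0 && b < 0) "COMMON_INCREASE"
    else if (a > 0 && b < 0) "SZ_UNIQUE_DECREASE"
    else if (a < 0 && b > 0) "ASD_UNIQUE_DECREASE"
    else "NONE"
  }, grid$ths, grid$tha)
  expect_identical(got, unname(oracle))
  # every ANOVA-passing feature lands in exactly one of the five classes
  expect_true(all(got %in% c(change_categories(), "NONE")))
  # failing the gate forces NONE
  expect_identical(unique(categorize_changes(cr, rep(FALSE, nrow(cr)))),
                   "NONE")
})

test_that("ASD-weaker flags use the SZ-vs-ASD sign within common changes", {
  cr <- data.frame(t_hc_sz = c(2, 2, -2, -2, 2, 2),
                   t_hc_asd = c(1, 1, -1, -1, -1, 1),
                   t_sz_asd = c(-0.7, 0.7, -0.7, 0.7, -0.7, 0))
  cats <- categorize_changes(cr, rep(TRUE, 6))
  wk <- asd_weaker_flags(cr, cats)
  expect_identical(wk[1], "ASD_WEAKER")    # common decrease, T(SZ-ASD) < 0
  expect_identical(wk[2], "NOT_WEAKER")
  expect_identical(wk[3], "NOT_WEAKER")    # common increase, T(SZ-ASD) < 0
  expect_identical(wk[4], "ASD_WEAKER")
  expect_true(is.na(wk[5]))                # unique category: undefined
  expect_identical(wk[6], "NOT_WEAKER")    # exact zero: strict inequality
})

test_that("summary percentages follow count / ANOVA-total arithmetic", {
  s <- change_summary(2592, 2906, 1013, 782, 2212, 2744, 7293)
  expect_equal(s$common_decrease_pct, 35.5)
  expect_equal(s$weaker_increase_pct, 94.4)
  s2 <- change_summary(191, 224, 17, 17, 172, 204, 449)
  expect_equal(s2$common_decrease_pct, 42.5)
  # all-NONE categorization: zero counts, zero percentages
  s3 <- summarize_table1(rep("NONE", 8), rep(NA_character_, 8),
                         total_anova = 8)
  expect_equal(s3$common_decrease_pct, 0)
  expect_equal(s3$common_decrease_n, 0L, ignore_attr = TRUE)
  expect_error(summarize_table1(rep("NONE", 3), rep(NA, 3)), "ANOVA")
})

test_that("the full engine recovers planted categories", {
  spec <- clean_spec(n_per_group_per_dataset = 150, n_features = 60,
                     effect_plan = make_effect_plan(12, magnitude = 0.8),
                     asd_scale = 0.5, seed = 19)
  ch <- generate_cohort(spec)
  res <- run_group_contrast(ch$measures, ch$covariates$group, family = "fnc")
  planted <- ch$truth$category != "NONE"
  expect_gte(mean(res$categories[planted] == ch$truth$category[planted]), 0.9)
  common_ok <- planted & res$categories == ch$truth$category &
    res$categories %in% c("COMMON_DECREASE", "COMMON_INCREASE")
  expect_gte(mean(res$weaker[common_ok] == "ASD_WEAKER"), 0.9)
  # summary is internally consistent
  expect_lte(res$summary$common_decrease_n + res$summary$common_increase_n +
             res$summary$sz_unique_decrease_n + res$summary$asd_unique_decrease_n,
             res$summary$total_anova)
})
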
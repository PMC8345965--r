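test_that("assay CV is 100 * sample sd / mean with guards", {
  expect_equal(assay_cv(rep(42, 5)), 0)
  expect_equal(assay_cv(c(50 - 4.15, 50, 50 + 4.15)), 8.3)   # sd 4.15, mean 50
  expect_equal(assay_cv(c(10, 20)), 100 * sd(c(10, 20)) / 15, tolerance = 1e-12)
  expect_equal(assay_cv(c(10, 20)), 47.14, tolerance = 1e-3)
  expect_error(assay_cv(5), "at least 2")
  expect_error(assay_cv(c(-1, 1)), "zero")
})

test_that("test selection follows the normality gate and variable type", {
  set.seed(8)
  norm1 <- rnorm(30, 10, 1); norm2 <- rnorm(30, 12, 1)
  skew1 <- rexp(50, 1); skew2 <- rexp(50, 0.5)
  mk <- function(a, b) data.frame(
    group = factor(rep(c("control", "ACS"), c(length(a), length(b))),
                   levels = c("control", "ACS")),
    v = c(a, b))
  gn <- compare_groups(mk(norm1, norm2), "v")
  expect_identical(gn$test_used, "t")
  expect_true(all(gn$shapiro_p > 0.05))
  gs <- compare_groups(mk(skew1, skew2), "v")
  expect_identical(gs$test_used, "mann_whitney")
  # one skewed group is enough to fall back to the rank test
  gm <- compare_groups(mk(norm1, skew2), "v")
  expect_identical(gm$test_used, "mann_whitney")
  # binary variables go to chi-squared
  gb <- compare_groups(mk(rbinom(30, 1, 0.2), rbinom(30, 1, 0.8)), "v")
  expect_identical(gb$test_used, "chi2")
  expect_error(compare_groups(mk(norm1, norm2), "missing_var"), "not found")
})

test_that("identical groups give null p-values and statin contrast is detected", {
  set.seed(9)
  x <- rnorm(20, 50, 5)
  same <- data.frame(group = factor(rep(c("control", "ACS"), each = 20),
                                    levels = c("control", "ACS")),
                     v = c(x, x))
  expect_gt(compare_groups(same, "v")$p_value, 0.9)
  # the study's statin contrast: 0/20 controls vs 21/24 cases, chi-squared
  statin <- data.frame(group = factor(rep(c("control", "ACS"), c(20, 24)),
                                      levels = c("control", "ACS")),
                       v = c(rep(0, 20), rep(1, 21), rep(0, 3)))
  gc <- compare_groups(statin, "v")
  expect_identical(gc$test_used, "chi2")
  expect_false(gc$fisher_fallback)
  expect_lt(gc$p_value, 0.001)
})

test_that("Fisher fallback triggers on sparse expected cells", {
  tab <- data.frame(group = factor(rep(c("control", "ACS"), c(6, 6)),
                                   levels = c("control", "ACS")),
                    v = c(rep(0, 6), rep(1, 2), rep(0, 4)))
  gc <- compare_groups(tab, "v")
  expect_true(gc$fisher_fallback)
})

test_that("stability score separates groups on the synthetic cohort", {
  co <- simulate_cohort(cohort_sim_params(seed = 3))
  gc <- compare_groups(co, "pct_denat_8h", test = "mann_whitney")
  expect_lt(gc$p_value, 0.001)
  med <- tapply(co$pct_denat_8h, co$group, median)
  expect_gt(med["ACS"], med["control"])
})

test_that("spearman screen is a rank statistic", {
  co <- simulate_cohort(cohort_sim_params(seed = 13))
  # self correlation is exactly 1
  sc <- spearman_screen(co, variables = "pct_denat_8h")
  expect_equal(sc$rho, 1)
  # invariance under strictly monotone transforms of either side
  co$bmi_t <- exp(co$bmi / 5)
  co$pct_log <- log(co$pct_denat_8h)
  a <- spearman_screen(co, variables = "bmi")$rho
  b <- spearman_screen(co, variables = "bmi_t")$rho
  expect_equal(a, b, tolerance = 1e-9)
  d <- spearman_screen(co, target = "pct_log", variables = "bmi")$rho
  expect_equal(a, d, tolerance = 1e-9)
  # constant covariate flagged, not crashed
  co$flat <- 1
  fc <- spearman_screen(co, variables = "flat")
  expect_true(is.na(fc$rho))
  expect_identical(fc$flag, "constant")
})

test_that("an independent noise covariate matches the null rank-correlation law", {
  # under independence, rho is approximately N(0, 1/(n-1)); at n = 44 the
  # chance of |rho| < 0.3 is 2*pnorm(0.3*sqrt(43)) - 1 = 0.951
  n_rep <- 200
  hits <- vapply(seq_len(n_rep), function(s) {
    co <- simulate_cohort(cohort_sim_params(seed = 300 + s))
    set.seed(9000 + s)
    co$noise <- rnorm(nrow(co))
    abs(spearman_screen(co, variables = "noise")$rho) < 0.3
  }, logical(1))
  p_null <- 2 * pnorm(0.3 * sqrt(43)) - 1
  expect_lt(abs(mean(hits) - p_null), 3 * sqrt(p_null * (1 - p_null) / n_rep))
})

test_that("partial correlation behaves at the no-confounder and degenerate limits", {
  set.seed(17)
  n <- 200
  tab <- data.frame(x = rnorm(n), y = rnorm(n), z = rbinom(n, 1, 0.5))
  tab$y <- 0.5 * tab$x + rnorm(n)
  marg <- cor(tab$x, tab$y)
  pc <- partial_correlation(tab, "x", target = "y", covariate = "z")
  expect_equal(pc$r, marg, tolerance = 0.05)
  # variable identical to the covariate: residual is null, r = 0
  tab$zx <- tab$z
  expect_equal(partial_correlation(tab, "zx", "y", "z")$r, 0)
  tab$const <- 1
  expect_error(partial_correlation(tab, "x", "y", "const"), "constant")
})

test_that("adjusting for the confounder shrinks a confounded association", {
  # association between x and y flows entirely through group-linked statin use
  shrunk <- vapply(1:200, function(s) {
    set.seed(400 + s)
    n <- 44
    z <- rbinom(n, 1, 0.5)
    x <- 2 * z + rnorm(n)
    y <- 3 * z + rnorm(n)
    tab <- data.frame(x = x, y = y, z = z)
    abs(partial_correlation(tab, "x", "y", "z")$r) < abs(cor(x, y))
  }, logical(1))
  expect_gte(mean(shrunk), 0.95)
})

test_that("lipid ratios divide per subject and summarize per group", {
  tab <- data.frame(subject_id = c("a", "b", "c"),
                    group = factor(c("control", "control", "ACS"),
                                   levels = c("control", "ACS")),
                    apo_a1 = c(100, 120, 90),
                    hdl_cholesterol = c(50, 60, 30),
                    hdl_triglycerides = c(25, 0, 30),
                    hdl_phospholipids = c(100, 100, 60))
  lr <- lipid_ratios(tab)
  expect_equal(lr$per_subject$apoa1_to_hdl_triglycerides[1], 4)
  expect_identical(lr$per_subject$flag[2], "zero_denominator")
  expect_true(is.na(lr$per_subject$apoa1_to_hdl_triglycerides[2]))
  # flagged subject excluded from the group summary (mean of ratios)
  s <- lr$summary
  ctrl_tg <- s[s$group == "control" & s$ratio == "apoa1_to_hdl_triglycerides", ]
  expect_equal(ctrl_tg$mean, 4)
  expect_equal(ctrl_tg$n, 1)
})

test_that("control apo A-I-to-HDL-triglycerides ratio recovers the calibrated level", {
  big <- simulate_cohort(cohort_sim_params(n_cases = 2000, n_controls = 2000,
                                           seed = 19))
  s <- lipid_ratios(big)$summary
  ctrl <- s[s$group == "control" & s$ratio == "apoa1_to_hdl_triglycerides", ]
  expect_lt(abs(ctrl$mean - 8.1), 0.6)
  acs <- s[s$group == "ACS" & s$ratio == "apoa1_to_hdl_triglycerides", ]
  expect_lt(acs$mean, ctrl$mean)   # patients' HDL enriched in triglycerides
})
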
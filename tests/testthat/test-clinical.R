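test_that("percent cell loss reproduces the reported arithmetic", {
  expect_equal(round(percent_cell_loss(2307, 122.2), 1), 5.3)
  expect_equal(percent_cell_loss(2334, 106.2), 4.550128, tolerance = 1e-6)
  expect_equal(percent_cell_loss(1234, 0), 0)
  expect_error(percent_cell_loss(0, 10), "positive")
  # scale invariance
  for (cc in c(0.5, 2, 10))
    expect_equal(percent_cell_loss(cc * 2334, cc * 106.2),
                 percent_cell_loss(2334, 106.2))
})

test_that("morphometry summary: hand-computed case and invariances", {
  ms <- morphometry_summary(c(400, 500), c(6, 5))
  expect_equal(ms$ave, 450)
  expect_equal(ms$sd, 70.71068, tolerance = 1e-6)
  expect_equal(ms$cv, 15.71348, tolerance = 1e-5)
  expect_equal(ms$hex_pct, 50)
  expect_equal(ms$ecd, 1e6 / 450)
  # constant areas: zero CV
  ms2 <- morphometry_summary(rep(450, 10))
  expect_equal(ms2$cv, 0)
  expect_equal(ms2$ave, 450)
  # CV invariant under area rescaling
  set.seed(1)
  a <- rlnorm(200, log(450), 0.3)
  expect_equal(morphometry_summary(2.5 * a)$cv, morphometry_summary(a)$cv)
  expect_error(morphometry_summary(numeric(0)), "non-empty")
  expect_error(morphometry_summary(c(1, 2), c(6)), "equal length")
})

test_that("morphometry recovers the reported preoperative pattern", {
  # areas drawn to match AVE 457.7, CV 34.7: summary recovers the spec
  set.seed(21)
  a <- pmax(rnorm(20000, 457.7, 0.347 * 457.7), 1)
  ms <- morphometry_summary(a)
  expect_lt(abs(ms$ave - 457.7), 5)
  expect_lt(abs(ms$cv - 34.7), 1)
})

test_that("normality screen routes as specified", {
  set.seed(11)
  expect_equal(normality_screen(rnorm(200))$route, "parametric")
  # heavily bimodal: two separated point masses, 100 seeds, >= 95% routed
  # to non-parametric handling
  non <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- c(rnorm(15, 0, 0.01), rnorm(15, 10, 0.01))
    non <- non + (normality_screen(x)$route == "nonparametric")
  }
  expect_gte(non, 95)
  expect_warning(sc <- normality_screen(rep(5, 10)), "constant")
  expect_equal(sc$route, "nonparametric")
  expect_error(normality_screen(c(1, 2)), "n >= 3")
})

test_that("group comparison: identical samples, routing, and options", {
  set.seed(2)
  a <- rnorm(30, 10, 2)
  r <- compare_groups(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  expect_equal(r$test, "Welch t")
  r2 <- compare_groups(a, a + 0.1, var_equal = TRUE)
  expect_equal(r2$test, "Student t")
  # non-normal samples go to the rank-sum route
  set.seed(3)
  b1 <- c(rnorm(15, 0, 0.01), rnorm(15, 10, 0.01))
  b2 <- c(rnorm(15, 0, 0.01), rnorm(15, 10, 0.01))
  expect_equal(compare_groups(b1, b2)$test, "Wilcoxon rank-sum")
  expect_equal(compare_groups(b1, b2, paired = TRUE,
                              paper_compat = TRUE)$test, "Friedman")
  expect_error(compare_groups(1:5, 1:4, paired = TRUE), "equal length")
})

test_that("matched ages stay non-significant across replicate cohorts", {
  sp <- cohort_spec()
  ns <- 0L
  for (s in 1:200) {
    co <- generate_cohort(sp, seed = 1000 + s)
    r <- compare_groups(co$age[co$group == "BSS"],
                        co$age[co$group == "Healon"], endpoint = "age")
    ns <- ns + !r$significant
  }
  expect_gte(ns / 200, 0.90)
})

test_that("type-I error of the two-group comparison is calibrated", {
  rej <- 0L
  set.seed(99)
  for (i in 1:2000) {
    a <- rnorm(30); b <- rnorm(30)
    rej <- rej + compare_groups(a, b)$significant
  }
  expect_lt(abs(rej / 2000 - 0.05), 0.02)
})

test_that("longitudinal course routes RM-ANOVA vs Friedman", {
  co <- generate_cohort(cohort_spec(), seed = 12)
  r <- longitudinal_course(co, "ecd", c("pre", "1d", "1w", "1m"),
                           group = "BSS")
  expect_true(r$test %in% c("RM-ANOVA", "Friedman"))
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  # forced non-normal data takes the Friedman route
  n <- 40
  co2 <- data.frame(group = "x",
                    e_a = c(rep(0, n / 2), rep(10, n / 2)) + rnorm(n, 0, 0.01),
                    e_b = c(rep(0, n / 2), rep(10, n / 2)) + rnorm(n, 0, 0.01),
                    e_c = c(rep(0, n / 2), rep(10, n / 2)) + rnorm(n, 0, 0.01))
  r2 <- longitudinal_course(co2, "e", c("a", "b", "c"))
  expect_equal(r2$test, "Friedman")
  expect_error(longitudinal_course(co, "ecd", c("pre", "1d")), "3 timepoints")
  expect_error(longitudinal_course(co, "xyz", c("pre", "1d", "1w")),
               "missing endpoint columns")
})

test_that("IOP peak counting is strict and group-aware", {
  expect_equal(iop_peak_count(data.frame(iop_6h = c(18, 21, 25, 20, 19))), 2)
  expect_equal(iop_peak_count(data.frame(iop_6h = rep(15, 8))), 0)
  expect_error(iop_peak_count(data.frame(iop_1d = 1)), "iop_6h")
  co <- generate_cohort(cohort_spec(), seed = 4)
  pk <- iop_peak_count(co)
  expect_named(pk, c("BSS", "Healon", "total"))
  expect_equal(unname(pk["total"]), unname(pk["BSS"] + pk["Healon"]))
})

test_that("the full endpoint report runs on a default cohort", {
  co <- generate_cohort(cohort_spec(), seed = 8)
  rep <- cohort_endpoint_report(co)
  expect_true(all(rep$comparisons$p_value >= 0 &
                    rep$comparisons$p_value <= 1))
  expect_named(rep$cell_loss_pct, c("BSS", "Healon"))
  expect_true(all(rep$cell_loss_pct > -5 & rep$cell_loss_pct < 15))
})
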
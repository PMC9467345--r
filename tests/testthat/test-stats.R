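test_that("t-test: degenerate, summary-vs-raw, and published-table cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(ttest_two_sample(x, x)$t, 0)
  expect_equal(ttest_two_sample(x, x)$p, 1)
  expect_error(ttest_two_sample(c(1, 1, 1), c(1, 1)), "undefined")

  set.seed(5)
  a <- stats::rnorm(12, 1); b <- stats::rnorm(9, 0.4)
  for (variant in c("student", "welch")) {
    via_raw <- ttest_two_sample(a, b, variant)
    via_sum <- ttest_two_sample(summary_stat(12, mean(a), stats::sd(a)),
                                summary_stat(9, mean(b), stats::sd(b)),
                                variant)
    expect_equal(via_raw$t, via_sum$t)
    expect_equal(via_raw$p, via_sum$p)
    ref <- stats::t.test(a, b, var.equal = variant == "student")
    expect_equal(via_raw$t, unname(ref$statistic))
    expect_equal(via_raw$p, ref$p.value)
  }

  # published cohort-characteristics row: ages similar between groups
  age <- ttest_two_sample(summary_stat(32, 62.5, 8.6),
                          summary_stat(30, 65.2, 9.9))
  expect_equal(age$p, 0.254, tolerance = 0.01 / 0.254)
  # published flow-void area row: clearly separated groups
  area <- ttest_two_sample(summary_stat(32, 1.16, 0.18),
                           summary_stat(30, 0.91, 0.16))
  expect_lt(area$p, 0.001)
})

test_that("chi-square on 2x2 tables matches the direct O/E formula", {
  same <- matrix(c(10, 20, 5, 10), 2)   # identical row proportions
  res <- chisq_2x2(same)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)

  sex <- matrix(c(25, 18, 7, 12), 2)    # published sex distribution
  expect_equal(chisq_2x2(sex)$p, 0.122, tolerance = 0.005 / 0.122)

  set.seed(8)
  for (i in 1:10) {
    tab <- matrix(stats::rpois(4, 12) + 1, 2)
    got <- chisq_2x2(tab)
    orc <- chisq_oracle(tab)
    expect_equal(got$chisq, orc$chisq, tolerance = 1e-12)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
  expect_error(chisq_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  # Yates correction shrinks the statistic
  expect_lt(chisq_2x2(sex, yates = TRUE)$chisq, chisq_2x2(sex)$chisq)
})

test_that("Pearson correlation: exact lines and null calibration", {
  x <- c(0.5, 1.3, 2.2, 3.1, 4.9)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 7)$r, -1)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(x[1:2], x[1:2]), "at least 3")

  set.seed(17)
  rs <- numeric(500); ps <- numeric(500)
  for (i in 1:500) {
    a <- stats::rnorm(25); b <- stats::rnorm(25)
    res <- pearson_r(a, b)
    rs[i] <- res$r; ps[i] <- res$p
  }
  expect_lt(abs(mean(rs)), 0.05)
  expect_gte(mean(ps < 0.05), 0.03)
  expect_lte(mean(ps < 0.05), 0.07)
})

test_that("partial correlation: reductions, degeneracies, and the recursive oracle", {
  set.seed(23)
  n <- 40
  x <- stats::rnorm(n); y <- stats::rnorm(n)
  expect_identical(partial_correlation(x, y, NULL), pearson_r(x, y))

  # a covariate orthogonal to x, y and the intercept leaves r untouched
  z <- stats::resid(stats::lm(stats::rnorm(n) ~ x + y))
  pr <- partial_correlation(x, y, cbind(z))
  expect_equal(pr$r, pearson_r(x, y)$r, tolerance = 1e-10)

  expect_error(partial_correlation(x, x, cbind(x)), "collinear")
  covs <- cbind(stats::rnorm(n), stats::rnorm(n))
  expect_error(partial_correlation(x, covs[, 1] * 2 + 1, covs),
               "residual is zero")

  for (i in 1:10) {
    a <- stats::rnorm(30); b <- stats::rnorm(30)
    zz <- cbind(stats::rnorm(30), stats::rnorm(30))
    got <- partial_correlation(a, b, zz)
    expect_equal(got$r, partial_r_oracle(a, b, zz), tolerance = 1e-10)
    expect_equal(got$df, 30 - 2 - 2)
  }
})

test_that("cohort report reproduces the table structure and group ordering", {
  coh <- generate_cohort(cohort_params(seed = 3))
  rep1 <- run_table_reports(coh)
  expect_s3_class(rep1, "cohort_report")
  expect_equal(rep1$characteristics$metric,
               c("Age (yr)", "Sex (M/F)", "Axial length (mm)", "SFCT (um)"))
  expect_equal(nrow(rep1$flow_voids), 3)
  # strong configured effects come out significant, adjusted and unadjusted
  expect_lt(rep1$flow_voids$p[2], 0.001)
  expect_lt(rep1$flow_voids$p_adjusted[2], 0.001)
  expect_false(is.null(rep1$pachyvessel_split))
  expect_equal(nrow(rep1$pachyvessel_split), 6)

  # deterministic: identical input gives byte-identical rendered reports
  rep2 <- run_table_reports(coh)
  d <- withr::local_tempdir()
  write_report(rep1, file.path(d, "a.md"), file.path(d, "a.json"))
  write_report(rep2, file.path(d, "b.md"), file.path(d, "b.json"))
  expect_identical(readLines(file.path(d, "a.md")),
                   readLines(file.path(d, "b.md")))
  expect_identical(readLines(file.path(d, "a.json")),
                   readLines(file.path(d, "b.json")))

  only <- generate_cohort(cohort_params(n_ppe = 0, n_control = 6, seed = 4))
  expect_message(rep_one <- run_table_reports(only), "one group")
  expect_true(all(is.na(rep_one$characteristics$p)))
})

test_that("flow-void group differences at published parameters are detected reliably", {
  # closed-form oracle: noncentral-t power of each test; the three metrics
  # are drawn independently, so the all-three rejection rate is the product
  power1 <- function(m1, s1, n1, m2, s2, n2, alpha = 0.001) {
    df <- n1 + n2 - 2
    ncp <- abs(m1 - m2) / sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df *
                                 (1 / n1 + 1 / n2))
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
  p_all <- power1(1483, 154, 32, 1826, 319, 30) *
    power1(1.16, 0.18, 32, 0.91, 0.16, 30) *
    power1(790, 144, 32, 520, 138, 30)
  expect_gte(p_all, 0.95)

  nseed <- 400
  hits <- 0
  for (s in seq_len(nseed)) {
    coh <- generate_cohort(cohort_params(seed = 10000 + s))
    ppe <- coh[coh$group == "PPE", ]; ctl <- coh[coh$group == "control", ]
    ps <- c(ttest_two_sample(ppe$n_voids, ctl$n_voids)$p,
            ttest_two_sample(ppe$total_void_area_mm2,
                             ctl$total_void_area_mm2)$p,
            ttest_two_sample(ppe$mean_void_size_um2,
                             ctl$mean_void_size_um2)$p)
    hits <- hits + all(ps < 0.001)
  }
  # simulated rate agrees with the analytic power to Monte-Carlo precision
  expect_lt(abs(hits / nseed - p_all), 3 * sqrt(p_all * (1 - p_all) / nseed))
})
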
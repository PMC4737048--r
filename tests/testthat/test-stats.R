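test_that("pooled t-test matches hand computation and degenerate cases", {
  r <- students_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  # pooled variance 5/3; t = -2 / sqrt(5/3 * 1/2) = -2.1909; df = 6
  expect_equal(r$statistic, -2.190890, tolerance = 1e-6)
  expect_equal(r$df, 6)
  same <- students_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  expect_error(students_t_test(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_error(students_t_test(1, c(1, 2)), "2 finite")
})

test_that("t and F p-values agree with numerical integration of the densities", {
  cases <- list(c(0.5, 3), c(1.3, 6), c(2.19, 6), c(3.4, 16), c(0.01, 50),
                c(5.5, 50))
  for (cs in cases) {
    p_pkg <- pbeta(cs[2] / (cs[2] + cs[1]^2), cs[2] / 2, 0.5)
    expect_equal(p_pkg, oracle_t_two_sided_p(cs[1], cs[2]), tolerance = 1e-8)
  }
  f_cases <- list(c(0.7, 2, 10), c(2.5, 2, 24), c(4.8, 3, 24), c(1.1, 4, 45))
  for (cs in f_cases) {
    p_pkg <- pbeta(cs[3] / (cs[3] + cs[2] * cs[1]), cs[3] / 2, cs[2] / 2)
    expect_equal(p_pkg, oracle_f_upper_p(cs[1], cs[2], cs[3]),
                 tolerance = 1e-8)
  }
  # and through the user-facing functions on a worked example
  withr::with_seed(8, {
    a <- rnorm(9)
    b <- rnorm(9, 0.5)
  })
  r <- students_t_test(a, b)
  expect_equal(r$p_value, oracle_t_two_sided_p(r$statistic, r$df),
               tolerance = 1e-8)
  r2 <- one_way_anova(list(a, b, a + 1))
  expect_equal(r2$p_value,
               oracle_f_upper_p(r2$statistic, r2$df[1], r2$df[2]),
               tolerance = 1e-8)
})

test_that("two-group ANOVA is the squared t-test", {
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- rnorm(7, 0, 2)
      b <- rnorm(5, 1, 2)
      tt <- students_t_test(a, b)
      ff <- one_way_anova(list(a, b))
      expect_equal(ff$statistic, tt$statistic^2, tolerance = 1e-10)
      expect_equal(ff$p_value, tt$p_value, tolerance = 1e-10)
    }
  })
})

test_that("ANOVA handles identical groups and degenerate variance", {
  r <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "undefined")
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
})

test_that("Welch variant relaxes the equal-variance assumption", {
  withr::with_seed(5, {
    a <- rnorm(20, 0, 1)
    b <- rnorm(6, 0, 8)
  })
  w <- students_t_test(a, b, var_equal = FALSE)
  ref <- t.test(a, b)  # Welch by default
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-8)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("fold change rescales onto the reference mean and preserves p-values", {
  expect_equal(fold_change(c(2, 4), c(1, 3)), c(1, 2))
  ref <- c(3, 5, 7)
  expect_equal(mean(fold_change(ref, ref)), 1)
  expect_error(fold_change(1:3, c(-1, 1)), "zero")
  withr::with_seed(13, {
    a <- rnorm(9, 10, 2)
    b <- rnorm(9, 12, 2)
  })
  p_raw <- students_t_test(a, b)$p_value
  p_fold <- students_t_test(fold_change(a, a), fold_change(b, a))$p_value
  expect_equal(p_fold, p_raw, tolerance = 1e-12)
})

test_that("reports assemble summaries and comparisons deterministically", {
  runs <- c(lapply(1:3, function(s) {
    analyze_trace(generate_trace(short_trace_spec(noise_sd = 0,
                                                  noise_rel = 0.02,
                                                  seed = s))$trace)
  }), lapply(4:6, function(s) {
    plan <- default_state_plan(rates = c(S2_PMG = 18, S3_PMG = 76,
                                         S3_PMGS = 188, S4_PMGS = 55,
                                         FCCP1 = 200, FCCP2 = 263,
                                         FCCP3 = 240), duration_s = 240)
    analyze_trace(generate_trace(trace_spec(state_plan = plan, noise_sd = 0,
                                            noise_rel = 0.02,
                                            seed = s))$trace)
  }))
  tab <- rates_table(runs, group_labels = rep(c("GK", "Wistar"), each = 3))
  rep1 <- build_report(rates = tab, comparisons = list(
    list(data = "respirometry", groups = c("GK", "Wistar"))))
  expect_identical(nrow(rep1$comparisons), 7L)  # six states + RCR
  expect_true(all(c("mean_GK", "sem_GK", "mean_Wistar", "sem_Wistar",
                    "p_value", "significant") %in% names(rep1$comparisons)))
  # summaries match an independent mean/SEM computation
  s3 <- tab$s3_pmgs[tab$group_label == "GK"]
  srow <- rep1$summaries$respirometry
  srow <- srow[srow$group_label == "GK" & srow$parameter == "s3_pmgs", ]
  expect_equal(srow$mean, mean(s3))
  expect_equal(srow$sem, sd(s3) / sqrt(3))

  # no comparisons: summaries only
  rep2 <- build_report(rates = tab)
  expect_null(rep2$comparisons)
  expect_error(build_report(rates = tab, comparisons = list(
    list(data = "respirometry", groups = c("GK", "Sprague")))),
    "unmatched.*Sprague")
})
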
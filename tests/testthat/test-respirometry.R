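test_that("flux derivation follows the chamber unit convention", {
  # constant concentration -> zero flux
  tr <- oxygraph_trace(time_s = 0:200, o2_nmol_per_ml = rep(150, 201),
                       events = data.frame(time_s = 0, label = "PMG"),
                       chamber_volume_ml = 2, cell_count_millions = 1)
  expect_true(all(concentration_to_flux(tr)$flux_pmol_s_per_million == 0))

  # linear decline 100 -> 90 nmol/mL over 100 s, 2 mL, 1e6 cells -> 200
  tr <- oxygraph_trace(time_s = 0:100, o2_nmol_per_ml = seq(100, 90, -0.1),
                       events = data.frame(time_s = 0, label = "PMG"),
                       chamber_volume_ml = 2, cell_count_millions = 1)
  flux <- concentration_to_flux(tr)$flux_pmol_s_per_million
  expect_equal(flux, rep(200, 101), tolerance = 1e-9)

  # per-chamber and per-million-cell dialects differ by the cell count
  tr$cell_count_millions <- 0.5
  expect_equal(concentration_to_flux(tr)$flux_pmol_s_per_million,
               rep(400, 101), tolerance = 1e-9)
})

test_that("flux derivation validates its inputs", {
  tr <- flux_trace(rep(1, 200))
  expect_error(concentration_to_flux(tr), "o2")
  jitter_t <- c(0, 1, 2, 3.5, 4, 5:50)
  tr2 <- oxygraph_trace(time_s = jitter_t,
                        o2_nmol_per_ml = seq_along(jitter_t),
                        events = data.frame(time_s = 0, label = "PMG"))
  expect_error(concentration_to_flux(tr2), "jitter")
})

test_that("plateau detection finds exactly the long stable stretches", {
  f <- rep(c(20, 150, 240, 50, 370), each = 300)
  segs <- detect_plateaus(flux_trace(f))
  expect_identical(nrow(segs), 5L)
  expect_equal(segs$mean_flux, c(20, 150, 240, 50, 370))
  expect_true(all(segs$cv == 0))

  # a 100-s stable stretch between ramps is below the 3-minute rule
  f2 <- c(seq(0, 100, length.out = 150), rep(100, 100),
          seq(100, 300, length.out = 150), rep(300, 400))
  segs2 <- detect_plateaus(flux_trace(f2))
  expect_true(all(segs2$mean_flux > 250))
})

test_that("state assignment takes the last plateau per window and max FCCP step", {
  segs <- data.frame(
    start_s = c(0, 400, 800, 1200, 1600, 2000, 2400),
    end_s = c(250, 650, 1050, 1450, 1850, 2250, 2650),
    mean_flux = c(30, 154, 241, 53, 300, 375, 350),
    slope = 0, cv = 0)
  events <- data.frame(
    time_s = c(0, 380, 780, 1180, 1580, 1980, 2380),
    label = c("PMG", "ADP", "SUCC", "OLIGO", "FCCP", "FCCP", "FCCP"))
  r <- assign_states(segs, events, end_time_s = 2700)
  expect_equal(r$s2_pmg, 30)
  expect_equal(r$s3_pmg, 154)
  expect_equal(r$s3_pmgs, 241)
  expect_equal(r$s4_pmgs, 53)
  # overdosed final step cannot drag the uncoupled estimate down
  expect_equal(r$uncoupled, 375)
  expect_true(is.na(r$cytc_rate))

  # two plateaus inside one window: the later one wins
  segs2 <- rbind(segs,
                 data.frame(start_s = 270, end_s = 370, mean_flux = 99,
                            slope = 0, cv = 0))
  r2 <- assign_states(segs2, events, end_time_s = 2700)
  expect_equal(r2$s2_pmg, 99)

  # result does not depend on segment ordering
  r3 <- assign_states(segs[sample(nrow(segs)), ], events, end_time_s = 2700)
  expect_equal(unclass(r3), unclass(r))

  bad <- events
  bad$label[2] <- "OLIGO"
  expect_error(assign_states(segs, bad, end_time_s = 2700), "protocol order")
  expect_error(assign_states(segs[0, ], events), "no plateaus")
})

test_that("noiseless traces round-trip to the planned rates and RCR exactly", {
  g <- generate_trace(trace_spec(noise_sd = 0, seed = 4))
  r <- analyze_trace(g$trace)
  expect_equal(r$s2_pmg, 30)
  expect_equal(r$s3_pmg, 154)
  expect_equal(r$s3_pmgs, 241)
  expect_equal(r$s4_pmgs, 53)
  expect_equal(r$uncoupled, 375)
  expect_equal(r$rcr, 241 / 53)
  expect_true(r$cytc_intact)
})

test_that("cell-count normalization converts chamber rates once and only once", {
  raw <- structure(list(s2_pmg = 20, s3_pmg = 80, s3_pmgs = 100, s4_pmgs = 25,
                        uncoupled = 150, cytc_rate = 101, rcr = NA_real_,
                        normalized = FALSE), class = "state_rates")
  out <- normalize_to_cells(raw, 0.5)
  expect_equal(out$s3_pmgs, 200)  # 100 pmol/s over 0.5e6 cells
  expect_equal(out$s4_pmgs, 50)
  expect_true(out$normalized)
  expect_error(normalize_to_cells(out, 0.5), "already normalized")
  expect_error(normalize_to_cells(raw, 0), "cell_count")
  ident <- normalize_to_cells(raw, 1)
  expect_equal(ident$s3_pmgs, raw$s3_pmgs)
})

test_that("RCR is the per-run state3/state4 ratio", {
  r <- structure(list(s3_pmgs = 200, s4_pmgs = 50, rcr = NA_real_,
                      normalized = TRUE), class = "state_rates")
  expect_equal(compute_rcr(r), 4)
  r$s3_pmgs <- 50
  expect_equal(compute_rcr(r), 1)
  r$s4_pmgs <- 0
  expect_error(compute_rcr(r), "> 0")
})

test_that("averaging per-run ratios differs from the ratio of group means", {
  # cohort group means for state 3 and 4 of 187.82 and 54.88 give a
  # mean-ratio of 3.42; a cohort whose per-run ratios average lower shows
  # why RCR must be formed per run before averaging
  withr::with_seed(42, {
    s3 <- rnorm(6, 187.82, 40)
    s4 <- rnorm(6, 54.88, 12)
  })
  per_run <- mean(s3 / s4)
  ratio_of_means <- mean(s3) / mean(s4)
  expect_gt(abs(per_run - ratio_of_means), 0.01)
  expect_equal(187.82 / 54.88, 3.4224, tolerance = 1e-4)
})

test_that("the cytochrome-c check flags membrane damage above the tolerance", {
  mk <- function(ref, cytc) structure(
    list(s3_pmgs = ref, cytc_rate = cytc, normalized = TRUE),
    class = "state_rates")
  expect_true(cytochrome_c_check(mk(200, 205)))    # +2.5%: intact
  expect_false(cytochrome_c_check(mk(200, 260)))   # +30%: damaged
  expect_error(cytochrome_c_check(mk(0, 10)), "> 0")
  expect_error(cytochrome_c_check(mk(200, NA)), "present")
  g <- generate_trace(trace_spec(noise_sd = 0, cytc_fractional_increase = 0.4,
                                 seed = 6))
  expect_false(analyze_trace(g$trace)$cytc_intact)
})

test_that("plateau means are stable under uniform resampling of the grid", {
  rates <- function(interval) {
    g <- generate_trace(short_trace_spec(noise_sd = 0, noise_rel = 0.01,
                                         sample_interval_s = interval,
                                         seed = 12))
    r <- analyze_trace(g$trace)
    c(r$s2_pmg, r$s3_pmg, r$s3_pmgs, r$s4_pmgs, r$uncoupled)
  }
  expect_equal(rates(0.5), rates(1), tolerance = 0.01)
})

test_that("state rates tabulate into the reporting schema", {
  runs <- lapply(1:3, function(s) {
    analyze_trace(generate_trace(short_trace_spec(seed = s))$trace)
  })
  tab <- rates_table(runs, group_labels = "GK")
  expect_identical(nrow(tab), 3L)
  expect_true(all(c("s2_pmg", "s3_pmg", "s3_pmgs", "s4_pmgs", "uncoupled",
                    "cytc_rate", "rcr") %in% names(tab)))
  expect_true(all(is.finite(tab$rcr)))
})
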
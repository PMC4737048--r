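make_bf <- function(nr = 10, nc = 10) {
  cyto <- matrix(TRUE, nr, nc)
  mito <- matrix(FALSE, nr, nc)
  nuc <- matrix(FALSE, nr, nc)
  list(cyto = cyto, mito = mito, nuc = nuc)
}

test_that("measure_field reproduces a hand-computed field", {
  p <- make_bf()
  p$mito[4:6, 4:6] <- TRUE     # one 3x3 square: area 9, perimeter 12
  p$nuc[1, 1] <- TRUE
  rec <- measure_field(binary_field(p$mito, p$cyto, p$nuc), "g", "f1")
  expect_identical(rec$n_mitochondria, 1L)
  expect_identical(rec$total_edge_length, 12L)
  expect_equal(rec$avg_perimeter_per_mito, 12)
  expect_identical(rec$total_network_area, 9L)
  expect_equal(rec$fraction_filled, 0.09)
  expect_equal(rec$mean_cell_size, 100)
  expect_equal(rec$avg_network_area_per_cell, 9)
  expect_equal(rec$avg_cytoplasm_area_per_cell, 100)
})

test_that("fill fraction is bounded and conservation holds", {
  p <- make_bf()
  p$nuc[1, 1] <- TRUE
  rec <- measure_field(binary_field(p$cyto, p$cyto, p$nuc), "g", "full")
  expect_equal(rec$fraction_filled, 1)
  withr::with_seed(77, {
    for (i in 1:20) {
      m <- random_mask(12, 12, runif(1, 0.1, 0.9))
      nuc <- matrix(FALSE, 12, 12)
      nuc[1, 1] <- TRUE
      r <- measure_field(binary_field(m, matrix(TRUE, 12, 12), nuc), "g", "f")
      if (r$n_mitochondria > 0)
        expect_identical(r$avg_perimeter_per_mito * r$n_mitochondria,
                         as.numeric(r$total_edge_length))
      expect_gte(r$fraction_filled, 0)
      expect_lte(r$fraction_filled, 1)
    }
  })
})

test_that("measuring generator truth masks reproduces the ground truth exactly", {
  for (s in 1:5) {
    f <- generate_field(fast_image_spec(seed = s))
    rec <- measure_field(f$truth, "g", "f")
    expect_identical(rec$n_mitochondria, f$truth$true_component_count)
    expect_identical(rec$total_edge_length, f$truth$true_edge_length)
    expect_identical(rec$total_network_area, f$truth$true_network_area)
    expect_identical(rec$total_cytoplasm_area, f$truth$true_cytoplasm_area)
    expect_identical(rec$n_nuclei, f$truth$true_n_nuclei)
  }
})

test_that("degenerate fields are rejected or flagged", {
  p <- make_bf()
  expect_error(measure_field(binary_field(p$mito, p$mito, p$nuc), "g", "f"),
               "cytoplasm")
  expect_error(measure_field(binary_field(p$mito, p$cyto, p$nuc), "g", "f"),
               "nuclei")
  p$nuc[1, 1] <- TRUE
  expect_warning(rec <- measure_field(binary_field(p$mito, p$cyto, p$nuc),
                                      "g", "f"), "empty mitochondrial")
  expect_identical(rec$n_mitochondria, 0L)
  expect_true(is.na(rec$avg_perimeter_per_mito))
})

fake_records <- function(sizes, fills, group = "g") {
  n <- length(sizes)
  data.frame(
    group_label = group, field_id = sprintf("f%02d", seq_len(n)),
    total_edge_length = 100L, n_mitochondria = 10L,
    avg_perimeter_per_mito = 10, total_network_area = 50L,
    total_cytoplasm_area = as.integer(round(sizes)), n_nuclei = 1L,
    fraction_filled = fills, fraction_filled_normalized = fills,
    avg_network_area_per_cell = 50, avg_cytoplasm_area_per_cell = sizes,
    mean_cell_size = sizes, stringsAsFactors = FALSE
  )
}

test_that("cell-size normalization collapses exact linear data to the median prediction", {
  sizes <- c(800, 1000, 1250, 1600, 2000)
  x <- 1 / sizes
  recs <- fake_records(sizes, 0.1 + 0.5 * x)
  out <- normalize_fill_fraction(recs)
  expect_equal(out$fraction_filled_normalized,
               rep(0.1 + 0.5 / median(sizes), 5), tolerance = 1e-12)
  # only the normalized column changes
  expect_identical(out$fraction_filled, recs$fraction_filled)
  expect_identical(out$avg_perimeter_per_mito, recs$avg_perimeter_per_mito)
})

test_that("normalization leaves identical-size groups untouched and decorrelates otherwise", {
  same <- fake_records(rep(1000, 4), c(0.1, 0.2, 0.15, 0.3))
  expect_message(out <- normalize_fill_fraction(same), "identity")
  expect_identical(out$fraction_filled_normalized, same$fraction_filled)

  withr::with_seed(99, {
    for (i in 1:10) {
      sizes <- runif(8, 500, 3000)
      fills <- 0.05 + 40 / sizes + rnorm(8, 0, 0.02)
      out <- normalize_fill_fraction(fake_records(sizes, fills))
      expect_lt(abs(cor(out$fraction_filled_normalized, 1 / sizes)), 1e-10)
    }
  })
  expect_error(normalize_fill_fraction(fake_records(c(1, 2), c(0.1, 0.2))),
               "3")
})

test_that("the two-SD rule discards exactly the gross outlier", {
  recs <- fake_records(rep(1000, 6), c(0, 0, 0, 0, 0, 100))
  # sample SD of [0,0,0,0,0,100] is 40.82; |100 - 16.67| / 40.82 = 2.04 > 2
  flt <- filter_outliers(recs)
  expect_identical(flt$discarded$field_id, "f06")
  expect_identical(nrow(flt$kept), 5L)
})

test_that("identical records are never discarded (zero-SD rule)", {
  recs <- fake_records(rep(1000, 5), rep(0.2, 5))
  flt <- filter_outliers(recs)
  expect_identical(nrow(flt$discarded), 0L)
  expect_identical(nrow(flt$kept), 5L)
})

test_that("an outlier in any single parameter suffices and order does not matter", {
  recs <- fake_records(rep(1000, 8), rep(0.2, 8))
  recs$n_nuclei <- c(rep(4L, 7L), 20L)  # outlying in exactly one parameter
  flt <- filter_outliers(recs)
  expect_identical(flt$discarded$field_id, "f08")
  shuffled <- recs[c(5, 1, 8, 3, 7, 2, 6, 4), ]
  flt2 <- filter_outliers(shuffled)
  expect_setequal(flt2$discarded$field_id, flt$discarded$field_id)
  expect_setequal(flt2$kept$field_id, flt$kept$field_id)
  expect_error(filter_outliers(recs[1, ]), "2")
})

test_that("group summaries report mean and SEM over retained records", {
  recs <- fake_records(rep(1000, 3), c(0.1, 0.2, 0.3))
  recs$avg_perimeter_per_mito <- c(1, 2, 3)
  gs <- summarize_group(recs)
  row <- gs$stats[gs$stats$parameter == "avg_perimeter_per_mito", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sem, 1 / sqrt(3))
  same <- fake_records(rep(1000, 3), rep(0.2, 3))
  gs2 <- summarize_group(same)
  expect_true(all(gs2$stats$sem == 0))
  expect_error(summarize_group(fake_records(1000, 0.2)), "2")
})

test_that("the pipeline filters before fitting the normalization", {
  # with n = 6 the single extreme field sits 2.04 SD out in fill fraction
  # and in cell size, so the single-pass rule removes it before the fit
  sizes <- c(900, 1000, 1100, 1200, 950, 5000)
  recs <- fake_records(sizes, c(0.2, 0.21, 0.19, 0.2, 0.2, 0.9))
  out <- morphometry_pipeline(recs)
  expect_identical(out$discarded$field_id, "f06")
  expect_identical(nrow(out$records), 5L)
  expect_identical(out$summary$discarded_field_ids, "f06")
  expect_identical(out$summary$counts$n_retained, 5L)
  expect_identical(out$summary$counts$n_discarded, 1L)
})
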
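test_that("dilution series cover the canonical protocol ranges", {
  std <- make_dilution_series()          # 10 ng/ul down to 1 zg/ul
  expect_length(std, 14L)
  expect_equal(log10(std), seq(1, -12))
  amo <- make_dilution_series(top = 8, bottom = 0.8e-12)
  expect_length(amo, 14L)
  expect_equal(amo[1], 8)
  expect_equal(amo[14], 0.8e-12, tolerance = 1e-12)
  expect_equal(make_dilution_series(top = 5, bottom = 5), 5)
  expect_error(make_dilution_series(top = 1, bottom = -1), "bottom > 0")
})

test_that("noiseless calibration recovers the ideal curve exactly", {
  model <- noiseless_model()  # slope -1/log10(2): 100% efficiency
  conc <- 10^seq(1, -5)       # all points comfortably above censoring
  series <- simulate_dilution_series(model, conc, replicates = 2, seed = 1)
  curve <- fit_standard_curve(series)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(curve$linear_range, range(conc))
  g <- glance(curve)
  expect_equal(g$n_points, length(conc))
})

test_that("censored bottom points are excluded from the linear range and LOD", {
  model <- noiseless_model()  # intercept 20, 50-cycle censoring at ~1e-9
  series <- simulate_dilution_series(model, seed = 2)
  expect_true(any(series$censored))
  curve <- fit_standard_curve(series)
  expect_equal(curve$linear_range[1], 1e-9)
  expect_equal(curve$lod, 1e-9)
  # censored concentrations sit below the accepted range
  cens <- unique(series$concentration[series$censored])
  expect_true(all(cens < curve$linear_range[1]))
})

test_that("standard-curve fitting recovers simulator parameters under noise", {
  # 3 replicates x 10 points, sigma 0.2 Ct, 50 seeded repetitions
  conc <- 10^seq(1, -8)
  model <- assay_model(slope = -3.32, intercept = 20, noise_sd = 0.2)
  slopes <- numeric(50)
  effs <- numeric(50)
  for (r in 1:50) {
    series <- simulate_dilution_series(model, conc, replicates = 3, seed = r)
    curve <- fit_standard_curve(series)
    slopes[r] <- curve$slope
    effs[r] <- curve$efficiency
  }
  expect_true(all(abs(slopes - (-3.32)) <= 0.1))
  expect_true(all(abs(effs - (10^(1 / 3.32) - 1)) <= 0.05))
})

test_that("concentration back-computation inverts the calibration", {
  model <- noiseless_model()
  series <- simulate_dilution_series(model, 10^seq(1, -5), seed = 1)
  curve <- fit_standard_curve(series)
  expect_equal(quantify_ct(curve$intercept, curve), 1)
  expect_equal(quantify_ct(curve$intercept + curve$slope, curve), 10)
  for (c0 in 10^seq(0, -5)) {
    ct <- model$intercept + model$slope * log10(c0)
    expect_equal(quantify_ct(ct, curve), c0, tolerance = 1e-9)
  }
})

test_that("noise filters apply the per-chemistry rules and are idempotent", {
  model <- noiseless_model()
  curve <- fit_standard_curve(simulate_dilution_series(model, 10^seq(1, -5),
                                                       seed = 1))
  recs <- amplification_records(
    well = c("A1", "A2", "A3", "B1", "B2", "B3"),
    assay_id = c("18s", "18s", "18s", "mir", "mir", "mir"),
    ct = c(35.0, 35.5, NA, 25, 45, NA),
    chemistry = c("genomic", "genomic", "genomic",
                  "smallrna", "smallrna", "smallrna")
  )
  out <- apply_noise_filters(recs, curves = list(mir = curve))
  expect_equal(out$noise_flag,
               c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$noise_reason[2], "ct_above_35")
  expect_equal(out$noise_reason[3], "censored")
  # Ct 45 back-computes below the fitted linear range
  expect_equal(out$noise_reason[5], "outside_linear_range")
  twice <- apply_noise_filters(out, curves = list(mir = curve))
  expect_identical(twice, out)
  expect_error(apply_noise_filters(recs, curves = list()), "no standard curve")
})

test_that("reference normalization is scale-invariant and local", {
  wells <- format_well_label(1, 1:5)
  t <- tibble::tibble(well = wells, ct = NA, censored = FALSE,
                      noise_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE),
                      quantity = c(2, 4, 6, 8, 10))
  r <- tibble::tibble(well = wells, ct = NA, censored = FALSE,
                      noise_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                      quantity = c(1, 2, 3, 4, 5))
  norm <- normalize_to_reference(t, r)
  expect_equal(norm$ratio, c(2, 2, 2, NA, 2))
  expect_equal(norm$valid, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  # identical grids give unit ratios
  self <- normalize_to_reference(t, t)
  expect_equal(self$ratio, rep(1, 5))
  # global rescaling cancels
  t2 <- t; t2$quantity <- t2$quantity * 7.3
  r2 <- r; r2$quantity <- r2$quantity * 7.3
  expect_equal(normalize_to_reference(t2, r2)$ratio, norm$ratio)
  expect_error(normalize_to_reference(t, dplyr::mutate(r, well = paste0("X", well))),
               "no wells")
})

test_that("delta-Ct normalization works without standard curves", {
  wells <- c("A1", "A2")
  t <- tibble::tibble(well = wells, ct = c(30, 28), censored = FALSE)
  r <- tibble::tibble(well = wells, ct = c(25, 25), censored = FALSE)
  norm <- normalize_to_reference(t, r, method = "delta_ct")
  expect_equal(norm$ratio, 2^(-c(5, 3)))
})

test_that("percent-of-max scaling matches the figure convention", {
  expect_equal(percent_of_max(c(2, 4, 8)), c(25, 50, 100))
  expect_equal(percent_of_max(c(3, 3, 3)), c(100, 100, 100))
  out <- percent_of_max(c(1, NA, 4))
  expect_equal(out, c(25, NA, 100))
  expect_true(all(out <= 100, na.rm = TRUE))
  expect_error(percent_of_max(c(NA_real_, NA_real_)), "no valid values")
})

test_that("cross-reactivity matrices are diagonal-100 with recoverable off-diagonals", {
  panel <- tidyr::expand_grid(primer_set = c("let7a", "let7c", "let7d"),
                              template = c("let7a", "let7c", "let7d")) |>
    dplyr::mutate(quantity = ifelse(primer_set == template, 50, 0))
  panel$quantity[panel$primer_set == "let7a" & panel$template == "let7d"] <- 1.5
  m <- cross_reactivity_matrix(panel)
  diag_vals <- m$percent[m$primer_set == m$template]
  expect_equal(diag_vals, rep(100, 3))
  expect_equal(m$percent[m$primer_set == "let7a" & m$template == "let7d"], 3)
  expect_equal(m$percent[m$primer_set == "let7c" & m$template == "let7a"], 0)
  # missing matched pair is an error
  bad <- panel[!(panel$primer_set == "let7d" & panel$template == "let7d"), ]
  expect_error(cross_reactivity_matrix(bad), "matched-pair")
})

test_that("plate-reader exports round-trip, including censored wells", {
  recs <- amplification_records(
    well = c("A1", "B1", "C1"), assay_id = "mir16",
    ct = c(24.123456, NA, 49.5), chemistry = "smallrna"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_ct(recs, path)
  back <- read_plate_ct(path)
  expect_equal(back$well, recs$well)
  expect_equal(back$assay_id, recs$assay_id)
  expect_equal(back$censored, recs$censored)
  expect_equal(back$ct, recs$ct, tolerance = 1e-6)
  expect_equal(back$chemistry, recs$chemistry)
  expect_equal(back$cycle_max, recs$cycle_max)
})

test_that("the SDS-dialect reader skips preambles and sniffs delimiters", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SDS 2.4 export", "Document: run42", "",
               "Well\tDetector\tCt",
               "A1\tmir16\t24.5",
               "A2\tmir16\tUndetermined"), path)
  recs <- read_plate_ct(path, chemistry = "smallrna")
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$ct, c(24.5, NA))
  expect_equal(recs$censored, c(FALSE, TRUE))
  noheader <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A1,mir16,24.5"), noheader)
  expect_error(read_plate_ct(noheader), "no header")
})
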
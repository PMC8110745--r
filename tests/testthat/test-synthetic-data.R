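test_that("frequency thresholds classify the synthetic SNP channels", {
  cfg <- flight_config(5e-3, 1e-4, stable_levy_model(0.5, 1e-4))
  sg <- seq(2000, 20000, by = 2000)

  # degenerate model: every mutation fixed
  all_fixed <- synth_ltee_timeseries(cfg, sg, seed = 2,
                                     freq_fun = function(n) rep(1, n))
  spm_total <- vapply(sg, function(s) {
    sum(all_fixed$catalog$type == "SPM" & all_fixed$catalog$generation <= s)
  }, numeric(1))
  expect_equal(all_fixed$series$fixed, spm_total)
  expect_equal(all_fixed$series$mean, spm_total)

  # nothing below the detection threshold reaches any channel
  synth <- synth_ltee_timeseries(cfg, sg, seed = 3)
  expect_true(all(unlist(synth$polymorphic) > 0.04))
  undetected <- synth$catalog$type == "SPM" & synth$catalog$frequency <= 0.04
  last <- length(sg)
  expect_equal(synth$series$fixed[last] + length(synth$polymorphic[[last]]),
               sum(synth$catalog$type == "SPM") - sum(undetected))
})

test_that("the fixed channel is a thinned Poisson stream of the SPM rate", {
  # frequencies uniform: P(f >= 0.96) = 0.04, so the fixed channel
  # accumulates at p_spm * 0.04
  cfg <- flight_config(2e-2, 0, stable_levy_model(0.5, 1e-4))
  sg <- seq(2000, 20000, by = 2000)
  set.seed(19)
  rates <- replicate(80, {
    s <- synth_ltee_timeseries(cfg, sg)$series
    estimate_rate(s$generation, s$fixed)$rate
  })
  truth <- 2e-2 * 0.04
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - truth), 3 * se)
})

test_that("hard censoring drops short events and nothing else", {
  m <- stable_levy_model(1.5, 1e-5)
  cat <- synth_cnv_catalog(m, 5000, detection = detection_model(floor = 5e3),
                           seed = 7)
  expect_length(cat$true, 5000)
  expect_true(all(cat$observed >= 5e3))
  expect_true(all(cat$true >= 10 & cat$true <= 2.4e8))
  # censoring never adds events, never alters surviving lengths
  expect_true(all(cat$observed %in% cat$true))
  expect_identical(cat$observed, cat$true[cat$true >= 5e3])
})

test_that("a soft detection model with gamma = 0 detects everything", {
  m <- stable_levy_model(1.5, 1e-5)
  cat <- synth_cnv_catalog(m, 2000,
                           detection = detection_model(mode = "soft", gamma = 0),
                           seed = 8)
  expect_identical(cat$observed, cat$true)
})

test_that("censoring below the window leaves the tail fit unchanged", {
  m <- stable_levy_model(1.5, 1e-5)
  cat <- synth_cnv_catalog(m, 1e5, detection = detection_model(floor = 5e3),
                           seed = 12)
  win <- c(1e5, Inf)
  f_true <- fit_powerlaw_tail(build_integrated(cat$true), window = win)
  f_obs <- fit_powerlaw_tail(build_integrated(cat$observed), window = win)
  # a hard floor below the window removes no event inside it, so the
  # rank-size points there are identical and the fit is unchanged exactly
  expect_equal(f_obs$nu, f_true$nu, tolerance = 1e-12)
  expect_equal(f_obs$pearson_r, f_true$pearson_r, tolerance = 1e-12)
})

test_that("CNV catalogs at the study parameters show the -3/2 integrated tail", {
  m <- stable_levy_model(1.5, 1e-5)
  cat <- synth_cnv_catalog(m, 1e5, detection = detection_model(mode = "soft",
                                                              gamma = 0),
                           seed = 14)
  d <- build_integrated(cat$true)
  keep <- d$lengths > 1e5
  slope <- loglog_slope(d$lengths[keep], d$counts[keep])
  expect_equal(slope, -1.5, tolerance = 0.1)
})

test_that("generators are seed-deterministic and round-trip through TSV", {
  m <- stable_levy_model(1.5, 1e-5)
  a <- synth_cnv_catalog(m, 1000, seed = 4)
  b <- synth_cnv_catalog(m, 1000, seed = 4)
  expect_identical(a, b)
  expect_error(synth_cnv_catalog(m, 10, bounds = c(100, 10)), "bounds")

  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  df <- data.frame(length_bp = a$observed)
  write_catalog(df, path)
  suppressMessages(back <- read_catalog(path))
  expect_equal(back$length_bp, a$observed)
})
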
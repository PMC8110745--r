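test_that("integrated distribution counts events at or above each length", {
  d <- build_integrated(c(5, 3, 8))
  expect_equal(d$lengths, c(3, 5, 8))
  expect_equal(d$counts, c(3, 2, 1))
  expect_equal(d$n_total, 3)

  dup <- build_integrated(c(7, 7, 7))
  expect_equal(dup$lengths, 7)
  expect_equal(dup$counts, 3)

  expect_error(build_integrated(numeric(0)), "empty")
  expect_error(build_integrated(c(2, 0.5)), ">= 1")
})

test_that("integrated counts are non-increasing and start at the total", {
  set.seed(11)
  for (i in 1:5) {
    l <- pmax(1, ceiling(rexp(500, 1e-3)))
    d <- build_integrated(l)
    expect_equal(d$counts[1], d$n_total)
    expect_true(all(diff(d$counts) < 0))
    expect_gte(d$counts[length(d$counts)], 1)
  }
})

test_that("power-law fit is exact on an exact power-law curve", {
  l <- 10^seq(1, 4, length.out = 20)
  counts <- 1000 * l^(-0.5)
  # build a distribution object directly carrying the exact curve
  d <- structure(list(lengths = l, counts = counts, n_total = 1000,
                      l_min = min(l), l_max = max(l)),
                 class = "integrated_distribution")
  fit <- fit_powerlaw_tail(d, window = c(1, 1e5))
  expect_equal(fit$nu, 0.5, tolerance = 1e-12)
  expect_equal(fit$c, 1000, tolerance = 1e-9)
  expect_equal(abs(fit$pearson_r), 1, tolerance = 1e-12)
  expect_lt(fit$objective, 1e-20)
})

test_that("power-law fit needs at least three points in the window", {
  d <- build_integrated(c(10, 100, 1000, 1e4))
  expect_error(fit_powerlaw_tail(d, window = c(50, 200)), "insufficient")
})

test_that("fits are invariant to input ordering and duplication order", {
  set.seed(4)
  l <- pmax(1, ceiling(levy_sample(stable_levy_model(0.5, 1e-4), 3000)))
  f1 <- fit_powerlaw_tail(build_integrated(l))
  f2 <- fit_powerlaw_tail(build_integrated(rev(l)))
  f3 <- fit_powerlaw_tail(build_integrated(sample(l)))
  expect_identical(f1, f2)
  expect_identical(f1, f3)
})

test_that("integrated Levy curve hits its boundary values and is monotone", {
  m <- stable_levy_model(0.5, 1e-4)
  l <- 10^seq(3, log10(5e6), length.out = 40)
  f <- eval_levy_integrated(m, l, l_min = 1e3, l_max = 5e6, n_total = 110)
  expect_equal(f[1], 110, tolerance = 1e-9)
  expect_equal(f[length(f)], 1, tolerance = 1e-9)
  expect_true(all(diff(f) < 0))
  expect_true(all(f >= 1 & f <= 110))
  expect_error(eval_levy_integrated(m, 10, 1e3, 5e6, 110), "within")
})

test_that("the Levy scale is recovered from catalogs of known scale", {
  # bacterial-like: nu = 1/2, alpha = 1e-4, observable range 1e3..5e6
  raw <- levy_sample(stable_levy_model(0.5, 1e-4), 4e4, seed = 21)
  l <- pmax(1, ceiling(raw))
  l <- l[l >= 1e3 & l <= 5e6][1:1e4]
  fit <- fit_levy_scale(build_integrated(l), nu = 0.5)
  expect_gt(fit$alpha, 1e-4 / 2)
  expect_lt(fit$alpha, 1e-4 * 2)

  # CNV-like: nu = 3/2, alpha = 1e-5
  raw <- levy_sample(stable_levy_model(1.5, 1e-5), 2e4, seed = 22)
  l <- pmax(1, ceiling(raw))
  l <- l[l >= 10 & l <= 2.4e8][1:1e4]
  fit <- fit_levy_scale(build_integrated(l), nu = 1.5)
  expect_gt(fit$alpha, 1e-5 / 2)
  expect_lt(fit$alpha, 1e-5 * 2)
})

test_that("degenerate catalogs cannot carry a Levy scale fit", {
  expect_error(fit_levy_scale(build_integrated(rep(100, 50)), 0.5),
               "insufficient")
})

test_that("decade histogram conserves counts and handles one bin", {
  one <- log_decade_histogram(runif(100, 10, 99.9))
  nonzero <- one[one$count > 0, ]
  expect_equal(nrow(nonzero), 1L)
  expect_equal(nonzero$density, 1 / 90, tolerance = 1e-12)

  set.seed(8)
  l <- pmax(1, ceiling(levy_sample(stable_levy_model(1.5, 1e-5), 5000)))
  h <- log_decade_histogram(l)
  expect_equal(sum(h$density * (h$l_hi - h$l_lo) * length(l)), length(l))
})

test_that("decade histogram tracks the model density in the tail", {
  m <- stable_levy_model(1.5, 1e-5)
  l <- pmax(1, ceiling(levy_sample(m, 1e5, seed = 31)))
  h <- log_decade_histogram(l)
  h <- h[h$l_lo >= 1e3 & h$count >= 50, ]
  # expected per-bp density of alpha*L_nu(alpha*l) averaged over each decade
  model <- (levy_survival(m$nu, m$alpha * h$l_lo) -
              levy_survival(m$nu, m$alpha * h$l_hi)) / (h$l_hi - h$l_lo)
  expect_equal(log10(h$density), log10(model), tolerance = 0.15)
})
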
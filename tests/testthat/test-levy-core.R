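test_that("model constructor enforces the parameter domain", {
  m <- stable_levy_model(0.5, 1e-4)
  expect_s3_class(m, "stable_levy_model")
  expect_error(stable_levy_model(0), "nu")
  expect_error(stable_levy_model(2.1), "nu")
  expect_error(stable_levy_model(1, -1), "alpha")
  expect_error(levy_pdf(3, 1), "stability index")
  expect_error(levy_pdf(1, -1), "non-negative")
})

test_that("density matches closed forms for the Cauchy and Gaussian indices", {
  y <- seq(0, 50, length.out = 101)
  expect_equal(levy_pdf(1, y), 2 / pi / (1 + y^2), tolerance = 1e-12)
  expect_equal(levy_pdf(2, y), exp(-y^2 / 4) / sqrt(pi), tolerance = 1e-12)
  # the quadrature engine itself (not the closed-form route) must agree too
  for (yy in c(0, 0.5, 1, 5, 20, 50)) {
    expect_equal(levymut:::.levy_pdf_quad(1, yy), 2 / pi / (1 + yy^2),
                 tolerance = 1e-6)
    expect_equal(levymut:::.levy_pdf_quad(2, yy), exp(-yy^2 / 4) / sqrt(pi),
                 tolerance = 1e-6)
  }
})

test_that("survival matches closed forms and its spot values", {
  expect_equal(levy_survival(0.7, 0), 1)
  expect_equal(levy_survival(1, 1), 0.5, tolerance = 1e-10)
  expect_equal(levy_survival(2, 2), 2 * pnorm(-sqrt(2)), tolerance = 1e-10)
  for (yy in c(0.5, 1, 5, 20)) {
    expect_equal(levymut:::.levy_surv_quad(1, yy), 1 - 2 / pi * atan(yy),
                 tolerance = 1e-6)
    expect_equal(levymut:::.levy_surv_quad(2, yy), 2 * pnorm(-yy / sqrt(2)),
                 tolerance = 1e-6)
  }
})

test_that("density and survival agree with an independent stable implementation", {
  for (nu in c("0.5", "1.5")) {
    p <- levy_pdf(as.numeric(nu), ref_levy$y)
    s <- levy_survival(as.numeric(nu), ref_levy$y)
    expect_equal(p, ref_levy$pdf[[nu]], tolerance = 1e-7)
    expect_equal(s, ref_levy$surv[[nu]], tolerance = 1e-6)
  }
})

test_that("density integrates to one", {
  for (nu in c(0.5, 1, 1.5, 2)) {
    norm <- integrate(function(y) levy_pdf(nu, y), 0, Inf,
                      rel.tol = 1e-8)$value
    expect_equal(norm, 1, tolerance = 1e-3)
  }
})

test_that("log-log tail slope of the density is -(nu + 1)", {
  y <- 10^seq(2, 4, length.out = 25)
  for (nu in c(0.5, 1, 1.5)) {
    expect_equal(loglog_slope(y, levy_pdf(nu, y)), -(nu + 1),
                 tolerance = 0.05)
  }
})

test_that("density agrees with its first-term asymptotic at large argument", {
  # the first correction is O(y^-nu) relative, so the 1e-3 regime starts
  # later for smaller indices
  ranges <- list(`0.5` = c(6, 8), `1` = c(2, 4), `1.5` = c(3, 5))
  for (nu in names(ranges)) {
    y <- 10^seq(ranges[[nu]][1], ranges[[nu]][2], length.out = 10)
    nv <- as.numeric(nu)
    asym <- 2 / pi * gamma(1 + nv) * sin(pi * nv / 2) * y^(-(1 + nv))
    expect_equal(levy_pdf(nv, y) / asym, rep(1, length(y)), tolerance = 1e-3)
  }
})

test_that("survival is strictly decreasing and bounded", {
  y <- 10^seq(-2, 1.3, length.out = 60)  # above ~20 the nu=2 tail underflows
  for (nu in c(0.4, 0.5, 1.3, 2)) {
    s <- levy_survival(nu, y)
    expect_true(all(diff(s) < 0))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("sampler draws match the survival oracle and closed-form moments", {
  m <- stable_levy_model(1, 1)
  x <- levy_sample(m, 1e5, seed = 0)
  grid <- 10^seq(-2, 2, length.out = 80)
  emp <- vapply(grid, function(g) mean(x >= g), numeric(1))
  expect_lt(max(abs(emp - levy_survival(1, grid))), 0.02)

  # half-Gaussian: E[l^2] = 2 for density exp(-l^2/4)/sqrt(pi)
  x2 <- levy_sample(stable_levy_model(2, 1), 1e5, seed = 1)
  expect_equal(mean(x2^2), 2, tolerance = 0.05)

  # nu = 1/2 draws against the numeric survival
  x5 <- levy_sample(stable_levy_model(0.5, 1), 1e5, seed = 2)
  grid <- 10^seq(-1, 3, length.out = 50)
  emp <- vapply(grid, function(g) mean(x5 >= g), numeric(1))
  expect_lt(max(abs(emp - levy_survival(0.5, grid))), 0.02)
})

test_that("the scale acts as a pure change of units on draws", {
  a <- levy_sample(stable_levy_model(0.7, 1), 1000, seed = 7)
  b <- levy_sample(stable_levy_model(0.7, 2e-3), 1000, seed = 7)
  expect_equal(b, a / 2e-3, tolerance = 1e-12)
})

test_that("sampling is reproducible and restores the caller's RNG state", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(levy_sample(stable_levy_model(1.5, 1), 10, seed = 99))
  expect_identical(runif(1), before)
  expect_identical(levy_sample(stable_levy_model(1.5, 1), 10, seed = 99),
                   levy_sample(stable_levy_model(1.5, 1), 10, seed = 99))
})
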
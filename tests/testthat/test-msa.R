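test_that("linearization maps blends to (m_z/m_x, (m_y/m_x)*r) points", {
  pts <- linearize(mel_pt_series())
  expect_equal(pts$x[1], 0)
  expect_equal(pts$y[1], (99.340 / 500.770) * 10.428, tolerance = 1e-12)
  expect_equal(round(pts$y[1], 4), 2.0686)

  # unit blend: equal masses, unit ratio
  s <- addition_series(
    data.frame(m_x = c(1, 1), m_y = c(1, 1), m_z = c(0, 1),
               r_obs = c(1, 2)), w_z = 1)
  expect_equal(linearize(s)$y[1], 1)
  expect_equal(linearize(s)$x, c(0, 1))

  pts5 <- linearize(cya_solution_series())
  expect_equal(pts5$x[2], 48.900 / 48.218, tolerance = 1e-12)
  expect_equal(round(pts5$x[2], 5), 1.01414)
})

test_that("series construction validates the blend table", {
  ok <- data.frame(m_x = c(1, 1), m_y = c(1, 1), m_z = c(0, 1),
                   r_obs = c(1, 2))
  expect_s3_class(addition_series(ok, 1), "addition_series")
  expect_error(addition_series(ok[1, ], 1), "at least 2")
  expect_error(addition_series(transform(ok, r_obs = c(-1, 2)), 1), "row 1")
  expect_error(addition_series(transform(ok, m_z = c(1, 2)), 1), "binary")
  expect_error(addition_series(transform(ok, m_z = c(0, 0)), 1), "ternary")
  expect_error(
    addition_series(ok, 1, isotopes = list(M_x = 126, M_y = 129, x_x1 = 1,
                                           x_x2 = 0, x_y1 = 1.2, x_y2 = 1)),
    "amount fractions")
})

test_that("general linearization reduces to the no-overlap form", {
  for (series in list(mel_solution_series(), mel_pt_series())) {
    plain <- linearize(series)
    series$isotopes <- list(M_x = 126.12, M_y = 129.10,
                            x_x1 = 1, x_x2 = 0, x_y1 = 0, x_y2 = 1)
    expect_equal(linearize_general(series), plain, tolerance = 1e-14)
  }
})

test_that("general linearization matches its closed form under overlap", {
  series <- mel_solution_series()
  series$isotopes <- list(M_x = 126.12, M_y = 129.10,
                          x_x1 = 1, x_x2 = 0, x_y1 = 0.01, x_y2 = 1)
  gen <- linearize_general(series)
  plain <- linearize(series)
  r_inv <- 1 / series$blends$r_obs
  # y scales by (x_y2 - r_inv*x_y1)/x_y2 relative to the no-overlap value
  expect_equal(gen$y, plain$y * (1 - r_inv * 0.01), tolerance = 1e-12)

  series$isotopes$x_x1 <- 0
  expect_error(linearize_general(series), "overlap inconsistent")
})

test_that("addition fit equals the normal-equations oracle", {
  set.seed(103)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    x <- c(0, sort(runif(n - 1, 0.1, 3)))
    y <- 1 + 1.5 * x + rnorm(n, 0, 0.05)
    fit <- fit_addition(data.frame(x = x, y = y))
    orc <- ols_oracle(x, y)
    expect_equal(fit$a0, orc[["a0"]], tolerance = 1e-10)
    expect_equal(fit$a1, orc[["a1"]], tolerance = 1e-10)
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-9 * sum(abs(y)))
  }
})

test_that("two exact points give an exact line", {
  fit <- fit_addition(data.frame(x = c(0, 1), y = c(1, 2)))
  expect_equal(fit$a0, 1)
  expect_equal(fit$a1, 1)
  expect_equal(fit$residuals, c(0, 0), tolerance = 1e-14)
  expect_error(fit_addition(data.frame(x = c(1, 1), y = c(1, 2))),
               "singular")
})

test_that("solution series reproduce their target content ratios", {
  mel <- msa_fit(mel_solution_series())
  cya <- msa_fit(cya_solution_series())
  expect_equal(round(mel$a0_over_a1, 3), 1.004)
  expect_equal(round(cya$a0_over_a1, 3), 0.994)
  # single-stock validation: w_z = 1, so w_x is the dimensionless ratio
  expect_equal(mel$w_x, mel$a0_over_a1)
})

test_that("matrix sample series reproduces intercept, slope and content", {
  res <- msa_fit(mel_pt_series())
  expect_equal(res$fit$a0, 2.0534, tolerance = 1e-4)
  expect_equal(round(res$fit$a1, 2), 1.62)
  expect_equal(round(res$w_x, 1), 12.8)
  expect_equal(msa_mass_fraction(res$fit, uq(10.08, 0.02)),
               res$fit$a0 / res$fit$a1 * 10.08)
})

test_that("identical slope and intercept recover w_z exactly", {
  s <- addition_series(
    data.frame(m_x = c(1, 1, 1), m_y = c(1, 1, 1), m_z = c(0, 1, 2),
               r_obs = c(1, 2, 3)), w_z = uq(7.7))
  res <- msa_fit(s)
  expect_equal(res$a0_over_a1, 1, tolerance = 1e-12)
  expect_equal(res$w_x, 7.7, tolerance = 1e-12)
})

test_that("a common instrument factor leaves a0/a1 invariant", {
  base <- msa_fit(mel_solution_series())
  for (f in c(0.5, 1.3, 4)) {
    # a common instrument factor on the observed A1/A2 ratios scales both
    # coefficients together and drops out of their ratio
    scaled <- msa_fit(scale_series_ratios(mel_solution_series(), f))
    expect_equal(scaled$fit$a0, base$fit$a0 * f, tolerance = 1e-12)
    expect_equal(scaled$fit$a1, base$fit$a1 * f, tolerance = 1e-12)
    expect_equal(scaled$a0_over_a1, base$a0_over_a1, tolerance = 1e-12)
  }
})

test_that("matching report summarises the blend ratios", {
  mel <- matching_report(mel_solution_series())
  expect_equal(round(mel$mean, 3), 1.221)
  expect_equal(round(mel$sd, 3), 0.008)
  expect_true(mel$matched)

  cya <- matching_report(cya_solution_series())
  expect_equal(round(cya$mean, 3), 1.056)
  expect_equal(round(cya$sd, 3), 0.008)

  const <- addition_series(
    data.frame(m_x = c(1, 1), m_y = c(1, 1), m_z = c(0, 1),
               r_obs = c(1.3, 1.3)), 1)
  expect_equal(matching_report(const)$sd, 0)
})

test_that("outlier exclusion refits on the remaining blends and is reported", {
  full <- msa_fit(mel_solution_series())
  sub <- msa_fit(mel_solution_series(), exclude = "2")
  expect_equal(sub$excluded, "2")
  expect_equal(nrow(sub$fit$points), 3L)
  expect_false(isTRUE(all.equal(sub$a0_over_a1, full$a0_over_a1)))
  expect_error(msa_fit(mel_solution_series(), exclude = c("1", "2", "3")),
               "too few")
})

test_that("broom-style accessors expose the fit", {
  fit <- msa_fit(mel_pt_series())$fit
  td <- tidy(fit)
  expect_equal(td$term, c("a0", "a1"))
  expect_equal(td$estimate, c(fit$a0, fit$a1))
  gl <- glance(fit)
  expect_equal(gl$a0_over_a1, fit$a0 / fit$a1)
  au <- augment(fit)
  expect_equal(au$.resid, au$y - au$.fitted, tolerance = 1e-12)
})
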
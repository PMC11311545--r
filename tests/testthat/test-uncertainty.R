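test_that("identity model has unit sensitivity and a single full index", {
  m <- model_spec(list(x = uq(3, 0.2)), function(v) c(y = v[["x"]]))
  b <- gum_budget(m)
  expect_equal(tidy(b)$c_i, 1, tolerance = 1e-8)
  expect_equal(tidy(b)$index, 1)
  expect_equal(glance(b)$u_c, 0.2, tolerance = 1e-8)
})

test_that("linear sum model matches closed-form propagation", {
  m <- model_spec(list(x = uq(1, 3), y = uq(2, 4)),
                  function(v) c(s = v[["x"]] + v[["y"]]))
  b <- gum_budget(m)
  expect_equal(glance(b)$u_c, 5, tolerance = 1e-6)
  expect_equal(tidy(b)$index, c(0.36, 0.64), tolerance = 1e-6)
  expect_equal(glance(b)$U, 10, tolerance = 1e-6)
})

test_that("budget indices sum to one for every output", {
  models <- list(
    emd_model(mel_pt_emd_pair()),
    msa_model(mel_pt_series()),
    msa_model(cya_solution_series())
  )
  for (m in models) {
    b <- tidy(gum_budget(m))
    sums <- as.numeric(tapply(b$index, b$output, sum))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  }
})

test_that("double-IDMS budget reproduces the published sensitivities", {
  b <- gum_budget(emd_model(mel_pt_emd_pair()))
  terms <- tidy(b)
  expect_equal(terms$c_i[terms$term == "r_b"], 12, tolerance = 0.02)
  expect_equal(terms$c_i[terms$term == "r_bc"], -13, tolerance = 0.02)
  expect_equal(terms$c_i[terms$term == "w_zc"], 1.2, tolerance = 0.05)
  expect_equal(terms$index[terms$term == "r_bc"], 0.55, tolerance = 0.01)
  expect_equal(round(glance(b)$u_c, 2), 0.52)
})

test_that("repeat scaling folds 1/sqrt(n) into the effective uncertainty", {
  b <- gum_budget(msa_model(mel_solution_series()), repeat_scaling = TRUE)
  terms <- tidy(b)
  wx_terms <- terms[terms$output == "w_x", ]
  r2 <- wx_terms[wx_terms$term == "r_2", ]
  expect_equal(r2$u_eff, r2$u / sqrt(3))
  # the noisiest ratio dominates the melamine solution budget
  expect_equal(r2$index, max(wx_terms$index))
  expect_gt(r2$index, 0.5)
  # report layout folds the repeat factor into the printed coefficient and
  # reproduces the published relative variance contribution of this ratio
  rep_tbl <- budget_report(b, "w_x")
  expect_equal(abs(rep_tbl$c_i[rep_tbl$Measurand == "r_2"]), 0.58,
               tolerance = 0.01)
  expect_equal(rep_tbl$ci2_ur2_1e5[rep_tbl$Measurand == "r_2"], 32.2,
               tolerance = 0.01)
  raw <- gum_budget(msa_model(mel_solution_series()), repeat_scaling = FALSE)
  raw2 <- tidy(raw)[tidy(raw)$output == "w_x" & tidy(raw)$term == "r_2", ]
  expect_equal(raw2$u_eff, raw2$u)
})

test_that("propagation failure names the offending input", {
  m <- model_spec(list(a = uq(1, 0.1), b = uq(0, 0.1)),
                  function(v) c(y = v[["a"]] + sqrt(v[["b"]])))
  expect_error(suppressWarnings(gum_budget(m)), "`b`")
})

test_that("monte carlo is exact for degenerate inputs and seeded draws repeat", {
  m <- model_spec(list(x = uq(3, 0), y = uq(4, 0)),
                  function(v) c(s = v[["x"]] * v[["y"]]))
  mc <- monte_carlo(m, n_draws = 200, seed = 1)
  expect_equal(mc$summary$mean, 12)
  expect_equal(mc$summary$sd, 0)
  expect_equal(mc$summary$q2.5, 12)

  m2 <- msa_model(mel_pt_series())
  a <- monte_carlo(m2, n_draws = 500, seed = 9, retain_samples = TRUE)
  b <- monte_carlo(m2, n_draws = 500, seed = 9, retain_samples = TRUE)
  expect_identical(a$summary, b$summary)
  expect_identical(a$samples, b$samples)
  c_ <- monte_carlo(m2, n_draws = 500, seed = 10)
  expect_false(identical(a$summary, c_$summary))
})

test_that("monte carlo of a linear model matches the analytic distribution", {
  m <- model_spec(list(x = uq(1, 3), y = uq(2, 4)),
                  function(v) c(s = v[["x"]] + v[["y"]]),
                  fn_matrix = function(d) cbind(s = d[, "x"] + d[, "y"]))
  n <- 20000
  mc <- monte_carlo(m, n_draws = n, seed = 4)
  se_mean <- 5 / sqrt(n)
  expect_lt(abs(mc$summary$mean - 3), 3 * se_mean)
  se_sd <- 5 / sqrt(2 * (n - 1))
  expect_lt(abs(mc$summary$sd - 5), 3 * se_sd)
  # GUM combined uncertainty agrees with the simulated sd for a linear model
  expect_lt(abs(glance(gum_budget(m))$u_c - mc$summary$sd), 3 * se_sd)
})

test_that("vectorized and looped evaluation agree draw by draw", {
  pair <- mel_pt_emd_pair()
  vec <- monte_carlo(emd_model(pair), n_draws = 2000, seed = 3,
                     retain_samples = TRUE)
  looped_model <- emd_model(pair)
  looped_model$fn_matrix <- NULL
  loop <- monte_carlo(looped_model, n_draws = 2000, seed = 3,
                      retain_samples = TRUE)
  expect_equal(vec$samples, loop$samples, tolerance = 1e-14)
})

test_that("failing draws are rejected and counted, with a warning over 1%", {
  m <- model_spec(list(x = uq(0.1, 1)),
                  function(v) {
                    if (v[["x"]] <= 0) stop("negative")
                    c(y = sqrt(v[["x"]]))
                  })
  expect_warning(mc <- monte_carlo(m, n_draws = 500, seed = 2), "rejected")
  expect_gt(mc$n_rejected, 0)
  expect_true(mc$rejection_warning)
  expect_true(all(is.finite(mc$summary$mean)))
})

test_that("the nested standard-addition model is right-skewed for the matrix sample", {
  mc <- monte_carlo(msa_model(mel_pt_series()), n_draws = 4000, seed = 5)
  s <- mc$summary
  wx <- s[s$output == "w_x", ]
  expect_gt(wx$mean, wx$median)
  # upper tail further from the median than the lower tail
  expect_gt(wx$q97.5 - wx$median, wx$median - wx$q2.5)
})

test_that("the standard-addition model exposes every mass, ratio and w_z", {
  m <- msa_model(mel_pt_series())
  expect_equal(nrow(m$inputs), 4 * 3 + 4 + 1)
  expect_setequal(m$output_names, c("a0", "a1", "a0_over_a1", "w_x"))
  # with all uncertainties zeroed every draw equals the deterministic fit
  z <- m
  z$inputs$u <- 0
  z <- model_spec(z$inputs, z$fn, z$output_names)
  mc <- monte_carlo(z, n_draws = 200, seed = 6)
  det <- msa_fit(mel_pt_series())
  expect_equal(mc$summary$mean[mc$summary$output == "a0"], det$fit$a0,
               tolerance = 1e-12)
  expect_equal(mc$summary$sd, rep(0, 4), tolerance = 1e-14)
})
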
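test_that("noise-free model data is recovered exactly, including published truths", {
  d <- exact_series(1, 1, c(0.25, 0.5, 1, 2, 4))
  f <- fit_median_effect(d)
  expect_equal(f$dm, 1, tolerance = 1e-12)
  expect_equal(f$m, 1, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)

  for (agent in names(ref_params)) {
    p <- ref_params[[agent]]
    d <- exact_series(p$dm, p$m, dose_grid(0.01, 1, 8), agent_id = agent)
    f <- fit_median_effect(d)
    expect_equal(f$dm, p$dm, tolerance = 1e-9)
    expect_equal(f$m, p$m, tolerance = 1e-9)
    expect_equal(f$r, 1, tolerance = 1e-9)
    expect_true(f$r_ok)
  }
})

test_that("the fit equals an independent closed-form OLS oracle to 1e-10 relative", {
  doses <- dose_grid(0.02, 2, 12)
  sim <- simulate_single_agent(
    dm = 0.3, m = 0.8, doses = doses,
    noise_sd = 0.1, replicates = 1, seed = 42
  )
  f <- fit_median_effect(sim)
  x <- log10(sim$dose)
  y <- log10(sim$fraction_affected / (1 - sim$fraction_affected))
  o <- ols_oracle(x, y)
  expect_equal(f$m, o$slope, tolerance = 1e-10)
  expect_equal(f$dm, 10^(-o$intercept / o$slope), tolerance = 1e-10)
  expect_equal(f$r, o$r, tolerance = 1e-10)
  expect_equal(f$m_se, o$slope_se, tolerance = 1e-10)
})

test_that("the OLS solution matches a grid-search squared-error minimizer", {
  sim <- simulate_single_agent(
    dm = 0.5, m = 1.2, doses = dose_grid(0.05, 5, 6),
    noise_sd = 0.15, replicates = 1, seed = 11
  )
  f <- fit_median_effect(sim)
  x <- log10(sim$dose)
  y <- log10(sim$fraction_affected / (1 - sim$fraction_affected))
  sse <- function(log_dm, m) sum((y - m * (x - log_dm))^2)
  log_dm_grid <- seq(log10(f$dm) - 0.05, log10(f$dm) + 0.05, length.out = 101)
  m_grid <- seq(f$m - 0.05, f$m + 0.05, length.out = 101)
  grid <- expand.grid(log_dm = log_dm_grid, m = m_grid)
  grid$sse <- mapply(sse, grid$log_dm, grid$m)
  best <- grid[which.min(grid$sse), ]
  expect_equal(best$log_dm, log10(f$dm), tolerance = 1e-3)
  expect_equal(best$m, f$m, tolerance = 1e-3)
})

test_that("dose rescaling scales Dm and leaves m and r unchanged", {
  sim <- simulate_single_agent(
    dm = 0.2, m = 0.7, doses = dose_grid(0.01, 1, 9),
    noise_sd = 0.08, replicates = 2, seed = 5
  )
  f0 <- fit_median_effect(sim)
  for (k in c(0.1, 3, 250)) {
    fk <- fit_median_effect(dplyr::mutate(sim, dose = dose * k))
    expect_equal(fk$dm, k * f0$dm, tolerance = 1e-9)
    expect_equal(fk$m, f0$m, tolerance = 1e-9)
    expect_equal(fk$r, f0$r, tolerance = 1e-9)
  }
})

test_that("the usability band excludes 0/100% points, and too few points is an informative error", {
  d <- tibble::tibble(
    dose = c(0.01, 0.1, 1, 10, 100),
    fraction_affected = c(0, 0.3, 0.5, 0.7, 1)
  )
  f <- fit_median_effect(d)
  expect_equal(f$n_used, 3L)
  expect_equal(nrow(f$excluded), 2L)
  expect_match(f$excluded$reason[1], "lower usability bound")

  d2 <- tibble::tibble(dose = c(0.1, 1, 10), fraction_affected = c(0.001, 0.5, 0.999))
  expect_error(fit_median_effect(d2), "excluded points.*dose 0.1")
  d3 <- tibble::tibble(dose = c(1, 1), fraction_affected = c(0.4, 0.6))
  expect_error(fit_median_effect(d3), "2 distinct doses|1 dose")
})

test_that("replicates enter individually by default and can be averaged per dose", {
  sim <- simulate_single_agent(
    dm = 1, m = 1, doses = c(0.5, 1, 2),
    noise_sd = 0.2, replicates = 4, seed = 3
  )
  f_all <- fit_median_effect(sim)
  f_avg <- fit_median_effect(sim, average_replicates = TRUE)
  expect_equal(f_all$n_used, 12L)
  expect_equal(f_avg$n_used, 3L)
  # the dose-wise mean of y preserves the OLS slope for a balanced design
  expect_equal(f_avg$m, f_all$m, tolerance = 1e-9)
})

test_that("multi-agent data requires an explicit agent choice", {
  d <- dplyr::bind_rows(
    exact_series(1, 1, c(0.5, 1, 2), "a"),
    exact_series(2, 1, c(0.5, 1, 2), "b")
  )
  expect_error(fit_median_effect(d), "2 agents")
  expect_equal(fit_median_effect(d, agent_id = "b")$dm, 2, tolerance = 1e-9)
  expect_error(fit_median_effect(d, agent_id = "zzz"), "not present")
})

test_that("compute_dx inverts the model: Dm at the median effect, oracle-checked elsewhere", {
  f1 <- me_fit(1, 1)
  expect_identical(compute_dx(f1, 0.5), 1)
  expect_equal(compute_dx(f1, 2 / 3), 2, tolerance = 1e-12)
  expect_identical(compute_dx(ref_fit("asiaticoside"), 0.5), ref_params$asiaticoside$dm)

  br <- ref_fit("bromelain")
  expect_equal(compute_dx(br, 0.9), bisect_dose(br$dm, br$m, 0.9), tolerance = 1e-8)
  expect_equal(round(compute_dx(br, 0.9), 2), 1.86)

  expect_error(compute_dx(br, 1), "strictly in")
  expect_error(compute_dx(br, 0), "strictly in")
  expect_error(compute_dx(me_fit(1, -0.5), 0.5), "non-physical")
})

test_that("predict_fa is the forward model and round-trips with compute_dx", {
  expect_equal(predict_fa(me_fit(2, 1.3), 2), 0.5, tolerance = 1e-12)
  expect_equal(predict_fa(me_fit(1, 2), 3), 9 / 10, tolerance = 1e-12)
  expect_error(predict_fa(me_fit(1, 1), 0), "> 0")

  set.seed(202)
  for (i in 1:100) {
    f <- me_fit(dm = 10^runif(1, -3, 2), m = runif(1, 0.2, 4))
    # doses spanning the informative part of the curve (fa in 0.01..0.99);
    # beyond it fa saturates and 1 - fa is no longer representable
    d <- compute_dx(f, runif(1, 0.01, 0.99))
    expect_equal(compute_dx(f, predict_fa(f, d)), d, tolerance = 1e-9)
    fa <- runif(1, 0.01, 0.99)
    expect_equal(predict_fa(f, compute_dx(f, fa)), fa, tolerance = 1e-9)
  }
})

test_that("dose-effect mappings are strictly monotone for positive slope", {
  f <- ref_fit("diosgenin")
  fa <- seq(0.02, 0.98, by = 0.02)
  expect_true(all(diff(compute_dx(f, fa)) > 0))
  doses <- dose_grid(1e-3, 1e2, 40)
  expect_true(all(diff(predict_fa(f, doses)) > 0))
})

test_that("tidy and glance expose the fit in broom form", {
  f <- fit_median_effect(exact_series(0.5, 1.5, dose_grid(0.05, 5, 7), "x"))
  td <- tidy(f)
  expect_equal(td$term, c("m", "intercept", "Dm"))
  expect_equal(td$estimate[td$term == "Dm"], f$dm)
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$r_ok)
  expect_equal(gl$n_used, 7L)
})
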
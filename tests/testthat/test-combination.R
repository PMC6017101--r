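test_that("the constant-ratio design reproduces the published concentration grid", {
  ic50 <- purrr::map_dbl(ref_params, "dm")
  for (phyto in c("amenthoflavone", "asiaticoside", "diosgenin")) {
    des <- make_design(ic50[["bromelain"]], ic50[[phyto]],
      multipliers = ref_design$multipliers,
      agent_ids = c("bromelain", phyto)
    )
    # printed values mix half-up rounding and truncation at the 4th decimal
    # (e.g. 0.18075 -> 0.1808 but 0.06286 -> 0.0628), so agreement is judged
    # to one unit in the last printed place
    tol <- 1e-4
    expect_true(all(abs(des$conc_1 - ref_design$bromelain) < tol))
    printed <- ref_design[[phyto]]
    keep <- if (phyto == "diosgenin") c(1, 3, 4, 5) else seq_along(printed) # 2x entry is a known typo
    expect_true(all(abs(des$conc_2[keep] - printed[keep]) < tol))
    if (phyto == "diosgenin") {
      expect_gt(abs(des$conc_2[2] - printed[2]), tol) # the flagged typo really is off
    }
    # design invariants: exact multiples, one fixed mixing ratio
    expect_equal(des$conc_1, des$multiplier * ic50[["bromelain"]])
    expect_equal(
      unique(round(des$conc_1 / des$conc_2, 12)),
      round(ic50[["bromelain"]] / ic50[[phyto]], 12)
    )
  }
  expect_error(make_design(1, 1, multipliers = numeric(0)), "non-empty")
  expect_error(make_design(-1, 1), "> 0")
})

test_that("the design writer emits a compounds-by-multipliers table rounded to 4 decimals", {
  des <- make_design(0.0723, 0.3143,
    agent_ids = c("bromelain", "asiaticoside"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(des, path)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(tbl$compound, c("bromelain", "asiaticoside"))
  expect_equal(tbl$x2.5_ic50, c(0.1808, 0.7858)) # half-up at the .xxx75 boundary
  expect_equal(ncol(tbl), 6L)
})

test_that("an equal-slope Loewe-additive mixture fits to the closed-form additive Dm", {
  dm1 <- 0.08; dm2 <- 0.4; m <- 0.9; ratio <- 0.3
  f1 <- me_fit(dm1, m, "a1"); f2 <- me_fit(dm2, m, "a2")
  sim <- simulate_combination(f1, f2, ratio,
    doses = dose_grid(0.01, 2, 10), true_ci = 1, noise_sd = 0, replicates = 1
  )
  mix <- fit_combination(sim, ratio, agent_ids = c("a1", "a2"))
  expect_equal(mix$m, m, tolerance = 1e-9)
  expect_equal(mix$dm, loewe_mix_dm(dm1, dm2, ratio), tolerance = 1e-9)
  # the split at the median effect satisfies the additivity identity
  expect_equal(mix$d1 / compute_dx(f1, 0.5) + mix$d2 / compute_dx(f2, 0.5), 1, tolerance = 1e-9)
  expect_equal(mix$d1 + mix$d2, mix$dm)
  expect_equal(mix$d1 / (mix$d1 + mix$d2), ratio)
  expect_error(fit_combination(sim, 1.2), "strictly in")
})

test_that("CI is 1 everywhere for an exact Loewe-additive mixture", {
  for (ratio in c(0.2, 0.5, 0.8)) {
    f1 <- me_fit(0.1, 1.4, "a1"); f2 <- me_fit(0.9, 1.4, "a2")
    sim <- simulate_combination(f1, f2, ratio,
      doses = dose_grid(0.02, 5, 8), true_ci = 1, noise_sd = 0, replicates = 1
    )
    mix <- fit_combination(sim, ratio)
    prof <- compute_ci(mix, f1, f2)
    expect_equal(nrow(prof), 99L)
    expect_true(all(abs(prof$ci - 1) < 1e-6))
    expect_true(all(prof$label == "additive"))
  }
})

test_that("CI and DRI satisfy their defining identities across the profile", {
  f1 <- ref_fit("bromelain"); f2 <- ref_fit("amenthoflavone")
  sim <- simulate_combination(f1, f2, 0.4,
    doses = dose_grid(0.01, 1, 8), true_ci = 1.6, noise_sd = 0, replicates = 1
  )
  mix <- fit_combination(sim, 0.4, agent_ids = c(f1$agent_id, f2$agent_id))
  prof <- compute_ci(mix, f1, f2)
  # CI = sum of reciprocal DRIs, to machine precision
  expect_equal(prof$ci, 1 / prof$dri1 + 1 / prof$dri2, tolerance = 1e-14)
  expect_equal(prof$ci, prof$d1 / prof$dx1 + prof$d2 / prof$dx2, tolerance = 1e-14)
  # constant component ratio everywhere on the grid
  expect_equal(prof$d1 / prof$d2, rep(0.4 / 0.6, nrow(prof)), tolerance = 1e-12)
  # doses increase monotonically along the effect grid
  expect_true(all(diff(prof$d_total) > 0))
  expect_true(all(diff(prof$dx1) > 0))
  expect_true(all(diff(prof$dx2) > 0))
  expect_error(compute_ci(mix, f1, f2, fa = numeric(0)), "empty")

  dri <- compute_dri(mix, f1, f2)
  expect_equal(dri$fa, c(0.5, 0.75, 0.9, 0.95))
  expect_equal(dri$ci, 1 / dri$dri1 + 1 / dri$dri2, tolerance = 1e-14)
  expect_equal(dri$favorable1, dri$dri1 > 1)
})

test_that("published parameter worked examples give the printed CI and DRI values", {
  br <- ref_fit("bromelain"); am <- ref_fit("amenthoflavone")
  # bromelain + amenthoflavone at the mixture median effect
  res <- compute_dri(NULL, br, am, levels = 0.5, d1 = 0.2437, d2 = 0.3655)
  expect_equal(res$ci, 0.2437 / 0.0723 + 0.3655 / 0.1079, tolerance = 1e-12)
  expect_equal(round(res$ci, 2), 6.76)
  expect_equal(classify_ci(res$ci), "antagonism")
  expect_equal(res$dri1, 0.0723 / 0.2437)
  expect_lt(abs(res$dri1 - 0.29), 0.02)
  expect_lt(abs(res$dri2 - 0.29), 0.02)
  expect_false(res$favorable1)

  # bromelain + asiaticoside: the asiaticoside component dose at the median effect
  as_fit <- ref_fit("asiaticoside")
  res2 <- compute_dri(NULL, br, as_fit, levels = 0.5, d1 = 0.020, d2 = 0.2911)
  expect_lt(abs(res2$dri2 - 1.07), 0.02)
  expect_true(res2$favorable2)
})

test_that("components at half their solo equipotent dose give CI of exactly 1", {
  f1 <- ref_fit("bromelain"); f2 <- ref_fit("diosgenin")
  for (fa in c(0.3, 0.5, 0.8)) {
    res <- compute_dri(NULL, f1, f2,
      levels = fa,
      d1 = compute_dx(f1, fa) / 2, d2 = compute_dx(f2, fa) / 2
    )
    expect_equal(res$ci, 1, tolerance = 1e-14)
    expect_equal(res$dri1, 2, tolerance = 1e-14)
  }
})

test_that("classification uses the tolerance band by default and the strict trichotomy on request", {
  expect_equal(
    classify_ci(c(0.5, 0.89, 0.9, 1.0, 1.1, 1.11, 6.76)),
    c("synergism", "synergism", "additive", "additive", "additive", "antagonism", "antagonism")
  )
  expect_equal(
    classify_ci(c(0.999, 1, 1.001), strict = TRUE),
    c("synergism", "additive", "antagonism")
  )
  expect_error(classify_ci(0), "> 0")
  expect_error(classify_ci(-2), "> 0")
})

test_that("pointwise CI agrees with the fitted profile on exact mixture data", {
  f1 <- me_fit(0.2, 1.1, "a1"); f2 <- me_fit(0.6, 1.1, "a2")
  sim <- simulate_combination(f1, f2, 0.5,
    doses = dose_grid(0.05, 2, 6), true_ci = 0.7, noise_sd = 0, replicates = 1
  )
  pw <- compute_ci_pointwise(sim, 0.5, f1, f2)
  expect_equal(nrow(pw), 6L)
  expect_true(all(abs(pw$ci - 0.7) < 1e-6))
  expect_true(all(pw$label == "synergism"))
})
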
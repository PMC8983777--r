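test_that("exact signal-dependent noise is recovered with zero SSE", {
  st <- exact_weber_stats(c(`2` = 0.2, `6` = 0.2, `20` = 0.2))
  fit <- fit_variance_model(st, "fixed_w")
  expect_equal(unname(coef(fit)), 0.2, tolerance = 1e-10)
  expect_lt(fit$sse, 1e-18)
  expect_equal(residuals(fit), rep(0, nrow(st)), tolerance = 1e-10)
})

test_that("flexible fit recovers per-size Weber fractions, fixed fit compromises", {
  w_true <- c(`2` = 0.25, `6` = 0.15, `20` = 0.10)
  st <- exact_weber_stats(w_true)
  flex <- fit_variance_model(st, "flexible_w")
  expect_equal(unname(coef(flex)), unname(w_true), tolerance = 1e-8)
  expect_lt(flex$sse, 1e-16)
  fixed <- fit_variance_model(st, "fixed_w")
  expect_gt(fixed$sse, flex$sse)
  expect_gt(coef(fixed)[["w"]], min(w_true))
  expect_lt(coef(fixed)[["w"]], max(w_true))
  # with one size the two models coincide
  one <- st[st$target_size_deg == 6, ]
  expect_equal(unname(coef(fit_variance_model(one, "flexible_w"))),
               unname(coef(fit_variance_model(one, "fixed_w"))))
})

test_that("gain-noise fit recovers (w_s, sigma) from simulated trials", {
  p <- gain_noise_params(w_s = 0.12, w_m = 0, sigma = 0.08,
                         gains = monkey_gains("R"))
  conds <- pursuit_conditions(directions = "right")
  tr <- simulate_pursuit_trials(p, conds, 2e4, seed = 21)
  st <- condition_stats(tr)
  fit <- fit_variance_model(st, "gain_noise")
  expect_equal(coef(fit)[["w_s"]], 0.12, tolerance = 0.05)
  expect_equal(coef(fit)[["sigma"]], 0.08, tolerance = 0.05)
  # on sigma = 0 data the gain-noise fit collapses onto the null fit
  p0 <- gain_noise_params(w_s = 0.12, w_m = 0, sigma = 0,
                          gains = monkey_gains("R"))
  st0 <- condition_stats(simulate_pursuit_trials(p0, conds, 2e4, seed = 22))
  g <- fit_variance_model(st0, "gain_noise")
  n0 <- fit_variance_model(st0, "no_gain_noise")
  expect_lt(coef(g)[["sigma"]], 0.02)
  expect_equal(g$sse, n0$sse, tolerance = 0.05)
  expect_lte(g$sse, n0$sse + 1e-12)  # extra parameter can only help the SSE
})

test_that("held-out RMSE matches the arithmetic definition and ignores order", {
  # 2 sizes x 2 held-out speeds with predictions {1,2,3,6} vs observed {1,2,3,4}
  st <- data.frame(target_size_deg = c(1, 1, 2, 2),
                   target_speed_degps = c(8, 16, 8, 16),
                   mean_degps = c(1, sqrt(2), sqrt(3), sqrt(6)),
                   var_degps2 = c(1, 2, 3, 4))
  fit <- structure(list(model = "fixed_w", coefficients = c(w = 1),
                        train_speeds = c(8, 16), stats = st),
                   class = "weber_fit")
  expect_equal(score_rmse(fit, st), 1)  # sqrt((0+0+0+4)/4)
  expect_equal(score_rmse(fit, st[sample(4), ]), 1)
  expect_error(score_rmse(fit, st[st$target_speed_degps == 8, ]),
               "absent")
})

test_that("training respects the train/test speed split", {
  st <- exact_weber_stats(c(`6` = 0.2))
  st$var_degps2[st$target_speed_degps %in% c(8, 16)] <- 99  # corrupt test set
  fit <- fit_variance_model(st, "fixed_w", train_speeds = c(4, 12, 20))
  expect_equal(coef(fit)[["w"]], 0.2, tolerance = 1e-8)
  expect_equal(sort(fit$train_speeds), c(4, 12, 20))
})

test_that("fits are invariant to condition order and size relabeling", {
  w_true <- c(`2` = 0.22, `6` = 0.14, `20` = 0.09)
  st <- exact_weber_stats(w_true)
  f1 <- fit_variance_model(st, "gain_noise")
  f2 <- fit_variance_model(st[rev(seq_len(nrow(st))), ], "gain_noise")
  expect_equal(coef(f1), coef(f2))
  # relabeling sizes permutes but does not change the flexible estimates
  st3 <- st
  st3$target_size_deg <- c(`2` = 6, `6` = 20, `20` = 2)[
    as.character(st$target_size_deg)]
  f3 <- fit_variance_model(st3, "flexible_w")
  expect_equal(sort(unname(coef(f3))),
               sort(unname(coef(fit_variance_model(st, "flexible_w")))))
})

test_that("effective Weber inference mirrors direct per-size fits", {
  p <- gain_noise_params(w_s = 0.1, w_m = 0, sigma = 0.06,
                         gains = monkey_gains("R"))
  conds <- pursuit_conditions(directions = "right")
  tr <- simulate_pursuit_trials(p, conds, 2e4, seed = 23)
  st <- condition_stats(tr)
  fit <- fit_variance_model(st, "gain_noise")
  gr <- fit_gain_regression(tr)
  eff <- infer_effective_weber(fit, gr)
  # monotone: smaller gain (smaller target) -> larger effective Weber fraction
  eff <- eff[order(eff$target_size_deg), ]
  expect_true(all(diff(eff$w_eff) < 0))
  # agreement with direct per-size fits on well-specified data
  direct <- coef(fit_variance_model(st, "flexible_w"))
  expect_equal(eff$w_eff, unname(direct[paste0("w_", eff$target_size_deg)]),
               tolerance = 0.1)
  # sigma = 0 maps every size to the same effective value
  fit0 <- structure(list(model = "gain_noise",
                         coefficients = c(w_s = 0.1, sigma = 0),
                         stats = st), class = "weber_fit")
  eff0 <- infer_effective_weber(fit0, gr)
  expect_equal(diff(range(eff0$w_eff)), 0)
  expect_error(infer_effective_weber(fit, c(`2` = 0.3)), "missing")
})

test_that("per-size bootstrap intervals cover the generating Weber fractions", {
  p <- gain_noise_params(w_s = 0.18, w_m = 0, sigma = 0,
                         gains = c(`6` = 0.5, `20` = 0.7))
  conds <- pursuit_conditions(sizes = c(6, 20), directions = "right")
  tr <- simulate_pursuit_trials(p, conds, 400, seed = 31)
  ci <- weber_size_cis(tr, n_boot = 100, seed = 32)
  for (nm in names(ci$w)) {
    expect_gt(0.18, ci$ci[1, nm] - 0.03)
    expect_lt(0.18, ci$ci[2, nm] + 0.03)
  }
  expect_false(ci$separated)  # equal generating w: no ordered separation
})
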
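test_that("vector-average speed estimate obeys its limits and symmetries", {
  nn <- data.frame(pref_dir = c(0, 90, -90), pref_speed = c(16, 8, 8))
  # silence decodes to zero
  est0 <- vector_average_speed(c(0, 0, 0), nn)
  expect_equal(est0$s_hat, 0)
  # single dominant neuron: s_hat -> log2 of its preferred speed
  est1 <- vector_average_speed(c(1e6, 0, 0), nn, nu = 0.05)
  expect_equal(est1$s_hat, 4, tolerance = 1e-4)
  expect_equal(est1$s_hat_v, 0)
  # equal up/down drive cancels the vertical component
  est2 <- vector_average_speed(c(0, 30, 30), nn)
  expect_equal(est2$s_hat_v, 0)
})

test_that("gain pathway is the normalised linear sum", {
  nn <- data.frame(pref_dir = c(0, 45), pref_speed = c(16, 2))
  expect_equal(gain_pathway(c(0, 0), nn, c_norm = 3), 0)
  expect_equal(gain_pathway(c(3, 0), nn, c_norm = 3), 4)  # MT = c, s' = 16
  g1 <- gain_pathway(c(10, 20), nn, c_norm = 5)
  expect_equal(gain_pathway(c(20, 40), nn, c_norm = 5), 2 * g1)
  expect_error(gain_pathway(c(1, 1), nn, NA), "calibrated")
})

test_that("calibration hits the target mean and scales linearly with drive", {
  pop <- small_population(seed = 61)
  cfg <- calibrate_decoder(pop, decoder_config(sigma = 0),
                           n_calibration_trials = 400, seed = 62)
  sim <- simulate_pursuit_behavior(
    pop, cfg, pursuit_conditions(sizes = 20, directions = "right"),
    400, seed = 63)
  expect_equal(mean(sim$eye_speed_degps), 10, tolerance = 0.1)
  # closed-form rescale: the initial c plays no role
  cfg2 <- decoder_config(sigma = 0)
  cfg2$c_norm <- 123
  cfg2 <- calibrate_decoder(pop, cfg2, n_calibration_trials = 400, seed = 62)
  expect_equal(cfg2$c_norm, cfg$c_norm)
  # halving every amplitude halves the population drive and therefore c
  pop_half <- pop
  pop_half$amplitude <- pop$amplitude / 2
  cfg_half <- calibrate_decoder(pop_half, decoder_config(sigma = 0),
                                n_calibration_trials = 400, seed = 62)
  expect_equal(cfg_half$c_norm / cfg$c_norm, 0.5, tolerance = 0.05)
})

test_that("simulated behavior composes the two pathways with gain noise", {
  pop <- small_population(seed = 64)
  cfg <- calibrate_decoder(pop, decoder_config(sigma = 0), 300, seed = 65)
  conds <- pursuit_conditions(directions = "right")
  sim <- simulate_pursuit_behavior(pop, cfg, conds, 150, seed = 66)
  # sigma = 0: m = G_MT * s_hat exactly, eta recorded as 0
  expect_equal(sim$eye_speed_degps, sim$g_mt * sim$s_hat)
  expect_true(all(sim$eta_g == 0))
  # mean output increases with speed at fixed size and with size at fixed speed
  mu <- tapply(sim$eye_speed_degps,
               sim[c("target_speed_degps", "target_size_deg")], mean)
  expect_true(all(apply(mu, 2, diff) > 0))
  expect_true(all(apply(mu, 1, diff) > 0))
  # reproducibility
  sim2 <- simulate_pursuit_behavior(pop, cfg, conds, 150, seed = 66)
  expect_identical(sim$eye_speed_degps, sim2$eye_speed_degps)
})

test_that("gain noise inflates variance everywhere and m stays unbiased", {
  pop <- small_population(seed = 67)
  cfg0 <- calibrate_decoder(pop, decoder_config(sigma = 0), 300, seed = 68)
  cfg1 <- cfg0
  cfg1$sigma <- 0.3
  conds <- pursuit_conditions(directions = "right")
  sim0 <- simulate_pursuit_behavior(pop, cfg0, conds, 250, seed = 69)
  sim1 <- simulate_pursuit_behavior(pop, cfg1, conds, 250, seed = 69)
  st0 <- condition_stats(sim0)
  st1 <- condition_stats(sim1)
  expect_true(all(st1$var_degps2 > st0$var_degps2))
  # eta_G is zero-mean: means match up to the gain-noise standard error
  expect_equal(st1$mean_degps, st0$mean_degps, tolerance = 0.2)
  # analysis of sigma = 0 behavior returns a near-zero fitted sigma
  an0 <- analyze_simulated_weber(sim0)
  an1 <- analyze_simulated_weber(sim1)
  expect_lt(coef(an0$gain_noise)[["sigma"]], 0.05)
  expect_gt(coef(an1$gain_noise)[["sigma"]],
            coef(an0$gain_noise)[["sigma"]])
})

test_that("neuron-behavior correlations select classes and detect independence", {
  pop <- small_population(seed = 70)
  cfg <- calibrate_decoder(pop, decoder_config(sigma = 0), 300, seed = 71)
  cond <- pursuit_conditions(speeds = 16, sizes = 20, directions = "right")
  sim <- simulate_pursuit_behavior(pop, cfg, cond, 300, seed = 72,
                                   keep_rates = TRUE)
  rates <- attr(sim, "rates")[[1]]
  cc <- mt_pursuit_correlations(rates, sim$eye_speed_degps, pop,
                                as.list(cond))
  dpd <- abs(pursuitgain:::wrap_angle(pop$pref_dir))
  expect_setequal(cc$id, pop$id[dpd <= 45 | dpd >= 135])
  # shuffling a neuron's rates across trials destroys its correlation
  set.seed(73)
  sh <- rates
  j <- cc$id[which.max(abs(cc$correlation))]
  sh[, j] <- sample(sh[, j])
  cc_sh <- mt_pursuit_correlations(sh, sim$eye_speed_degps, pop,
                                   as.list(cond))
  # ~3.5 standard errors of a null correlation at n = 300
  expect_lt(abs(cc_sh$correlation[cc_sh$id == j]), 0.2)
  # negative correlations live almost entirely in the null-direction class
  neg <- cc[!is.na(cc$correlation) & cc$correlation < -0.1, ]
  if (nrow(neg) > 0)
    expect_gte(mean(neg$class == "null"), 0.75)
  expect_error(mt_pursuit_correlations(rates[1:20, ],
                                       sim$eye_speed_degps[1:20], pop,
                                       as.list(cond)), ">= 50")
})
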
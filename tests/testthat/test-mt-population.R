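test_that("population construction honours counts, ranges and the RF-size law", {
  pop <- mt_population(seed = 50)
  expect_equal(nrow(pop), 1280)
  expect_equal(sum(pop$ecc < 1), 180)
  expect_true(all(pop$dir_width >= 20 & pop$dir_width <= 90))
  expect_true(all(pop$speed_width >= 0.64 & pop$speed_width <= 2.8))
  expect_true(all(pop$pref_speed >= 0.5 & pop$pref_speed <= 256))
  expect_true(all(pop$amplitude >= 20 & pop$amplitude <= 200))
  expect_true(all(pop$ecc >= 0.25 & pop$ecc <= 30))
  expect_equal(pop$rf_diameter, (0.69 * pop$ecc + 1) / sqrt(pi))
  expect_equal(pop$surround_radius, 3 * pop$rf_diameter / 2)
})

test_that("peripheral eccentricities follow the ecc^-0.9 density", {
  cfg <- mt_config(n_total = 20180, n_foveal = 180)
  pop <- mt_population(cfg, seed = 51)
  per <- pop$ecc[pop$ecc >= 1]
  # analytic CDF of density ecc^-0.9 on [1, 30]: (e^0.1 - 1) / (30^0.1 - 1)
  cdf <- function(e) (e^0.1 - 1) / (30^0.1 - 1)
  ks <- suppressWarnings(ks.test(per, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("direction tuning evaluates the wrapped Gaussian", {
  nn <- data.frame(pref_dir = c(30, 30, 170), dir_width = c(40, 40, 20))
  expect_equal(direction_tuning(nn, 30)[1], 1)
  expect_equal(direction_tuning(nn[2, ], 70), exp(-0.5))
  # wrap: 170 vs -170 is a 20-deg difference
  expect_equal(direction_tuning(nn[3, ], -170), exp(-0.5))
})

test_that("speed tuning is log2-Gaussian and symmetric in octaves", {
  nn <- data.frame(pref_speed = 8, speed_width = 1)
  expect_equal(speed_tuning(nn, 8), 1)
  expect_equal(speed_tuning(nn, 16), exp(-0.5))
  expect_equal(speed_tuning(nn, 4), speed_tuning(nn, 16))
  expect_error(speed_tuning(nn, 0), "> 0")
})

test_that("receptive-field overlap uses exact lens geometry", {
  rf <- 2  # CRF diameter
  nn <- data.frame(x = 0, y = 0, ecc = 0, rf_diameter = rf,
                   surround_radius = 3)
  cfg <- mt_config()
  # stimulus engulfing CRF and surround
  ov <- rf_overlap(nn, rho = 100, cfg)
  expect_equal(ov$z, 1)
  expect_equal(ov$z_sur, 1)
  # concentric stimulus with radius CRF_radius / sqrt(2) covers half the CRF
  ov2 <- rf_overlap(nn, rho = rf / sqrt(2), cfg)
  expect_equal(ov2$z, 0.5)
  # disjoint stimulus
  nn_far <- transform(nn, x = 50, ecc = 50)
  ov3 <- rf_overlap(nn_far, rho = 2, cfg)
  expect_equal(ov3$z, 0)
  expect_equal(ov3$z_sur, 0)
  # stimulus covering the CRF exactly leaves the annulus untouched
  ov4 <- rf_overlap(nn, rho = rf, cfg)
  expect_equal(ov4$z, 1)
  expect_equal(ov4$z_sur, 0)
})

test_that("threshold nonlinearity and surround normalisation match hand values", {
  expect_equal(thresholded_response(0.25, 0, 1), 0.5)
  expect_equal(thresholded_response(1, 0.3, 2), 1)
  expect_equal(thresholded_response(0.25, 0.5, 1), 0)
  expect_error(thresholded_response(0.25, 1), "omega")
  expect_error(thresholded_response(1.5), "0, 1")
  expect_equal(surround_normalization(0.7, 0.9, beta = 0), 0.7)
  expect_equal(surround_normalization(1, 0, beta = 1, epsilon = 0.5), 1)
  expect_equal(surround_normalization(1, 1, beta = 1, epsilon = 0.5), 2 / 3)
})

test_that("mean response is the product of amplitude and tuning factors", {
  nn <- data.frame(id = 1, pref_dir = 0, dir_width = 60, pref_speed = 12,
                   speed_width = 1.5, amplitude = 100, ecc = 0.5,
                   x = 0.5, y = 0)
  nn$rf_diameter <- (0.69 * nn$ecc + 1) / sqrt(pi)
  nn$surround_radius <- 3 * nn$rf_diameter / 2
  cond_opt <- list(direction = "right", target_speed_degps = 12,
                   target_size_deg = 40)
  f <- mean_response(nn, cond_opt, mt_config())
  # fully covered CRF and surround: f_rho = 1/(0.5 + 1) = 2/3 at beta = 1
  expect_equal(f, 100 * 2 / 3)
  # orthogonal-direction stimulus: response suppressed by the tuning factor
  f_orth <- mean_response(nn, list(direction = 90, target_speed_degps = 12,
                                   target_size_deg = 40), mt_config())
  expect_equal(f_orth, f * exp(-90^2 / (2 * 60^2)))
  # hand product for a non-trivial case
  cond <- list(direction = "right", target_speed_degps = 6,
               target_size_deg = 2)
  ov <- rf_overlap(nn, 2, mt_config())
  f_rho <- surround_normalization(sqrt(ov$z), sqrt(ov$z_sur))
  expect_equal(mean_response(nn, cond, mt_config()),
               100 * direction_tuning(nn, 0) * speed_tuning(nn, 6) * f_rho)
})

test_that("mean response never exceeds the amplitude and shrinks with surround drive", {
  pop <- small_population(seed = 52)
  cfg <- attr(pop, "config")
  for (rho in c(2, 6, 20)) {
    f <- mean_response(pop, list(direction = "right",
                                 target_speed_degps = 12,
                                 target_size_deg = rho), cfg)
    expect_true(all(f >= 0 & f <= pop$amplitude + 1e-12))
  }
  # once the CRF is covered, growing the stimulus only recruits suppression
  nn <- pop[which.min(pop$ecc), , drop = FALSE]
  cover <- 2 * (sqrt(nn$x^2 + nn$y^2) + nn$rf_diameter / 2)
  sizes <- cover * c(1, 1.5, 2.5, 4)
  fs <- vapply(sizes, function(rho)
    mean_response(nn, list(direction = "right", target_speed_degps = 12,
                           target_size_deg = rho), cfg), numeric(1))
  expect_true(all(diff(fs) <= 1e-12))
  # but summed population activity still grows with patch size
  tot <- vapply(c(2, 6, 20), function(rho)
    sum(mean_response(pop, list(direction = "right", target_speed_degps = 12,
                                target_size_deg = rho), cfg)), numeric(1))
  expect_true(all(diff(tot) > 0))
})

test_that("correlation matrix matches the kernel and stays a correlation matrix", {
  pair <- identical_pair()
  R <- mt_correlations(pair)
  expect_equal(R[1, 2], 0.55)
  expect_equal(diag(R), c(1, 1))
  # opposite preferred directions, same speed and position
  pair2 <- pair
  pair2$pref_dir <- c(0, 180)
  R2 <- mt_correlations(pair2)
  expect_equal(R2[1, 2], 0.55 * exp(-1 / 0.4^2), tolerance = 1e-10)
  pop <- small_population(seed = 53)
  Rp <- mt_correlations(pop)
  expect_true(isSymmetric(Rp))
  expect_equal(diag(Rp), rep(1, nrow(pop)))
  ev <- eigen(Rp, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_lt(attr(Rp, "repair_frobenius") / sqrt(sum(Rp^2)), 0.01)
})

test_that("sampled responses have Poisson-like variance and target correlations", {
  pair <- identical_pair()
  cond <- list(direction = "right", target_speed_degps = 16,
               target_size_deg = 20)
  resp <- sample_responses(pair, cond, 8000, seed = 54, rectify = FALSE)
  f <- resp$mean_rates
  expect_true(all(f >= 20))
  for (j in 1:2) {
    v <- var(resp$rates[, j])
    se <- sd((resp$rates[, j] - mean(resp$rates[, j]))^2) / sqrt(8000)
    expect_lt(abs(v - f[j]), 3 * se)
  }
  expect_equal(cor(resp$rates[, 1], resp$rates[, 2]), 0.55, tolerance = 0.03)
  # determinism and rectification
  again <- sample_responses(pair, cond, 8000, seed = 54, rectify = FALSE)
  expect_identical(resp$rates, again$rates)
  rect <- sample_responses(pair, cond, 100, seed = 55)
  expect_true(all(rect$rates >= 0))
})

test_that("empirical pairwise correlations track the model kernel", {
  pop <- small_population(n = 40, n_foveal = 10, seed = 56)
  cfg <- attr(pop, "config")
  cond <- list(direction = "right", target_speed_degps = 12,
               target_size_deg = 20)
  R <- mt_correlations(pop, cfg)
  resp <- sample_responses(pop, cond, 6000, cfg, seed = 57, rectify = FALSE)
  f <- resp$mean_rates
  act <- which(f >= 20)
  emp <- cor(resp$rates[, act])
  tgt <- R[act, act]
  off <- upper.tri(emp)
  # 3 standard errors for a correlation estimate at n = 6000 is about 0.04
  expect_lt(max(abs(emp[off] - tgt[off])), 0.06)
})
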
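test_that("ensembles regenerate bit-identically from their seed", {
  s <- ensemble_spec(n_neurons = 20, radius = 1.5, seed = 42)
  e1 <- build_ensemble(s)
  e2 <- build_ensemble(s)
  expect_identical(e1, e2)
  e3 <- build_ensemble(ensemble_spec(20, 1.5, seed = 43))
  expect_false(identical(e1$gain, e3$gain))
})

test_that("rectified-linear tuning curves are nonnegative and monotone for e = +1", {
  ens <- build_ensemble(ensemble_spec(20, 1, seed = 1))
  A <- ensemble_rates(ens, seq(-1, 1, length.out = 101))
  expect_equal(ncol(A), 20L)
  expect_true(all(A >= 0))

  one <- build_ensemble(ensemble_spec(1, 1, seed = 2))
  one$encoders <- 1
  r <- decode_rate(one, 1, seq(-1, 1, length.out = 50))
  expect_true(all(diff(r) >= 0))
})

test_that("least-squares decoders reconstruct targets with the expected structure", {
  ens <- build_ensemble(ensemble_spec(100, 1, seed = 7))
  d0 <- solve_decoders(ens, target_fn = function(x) 0 * x)
  expect_lt(max(abs(d0)), 1e-8)

  d <- solve_decoders(ens)
  expect_equal(decode_rate(ens, d, 0.5), 0.5, tolerance = 0.05)

  # linearity: scaling the target scales the decoders
  d3 <- solve_decoders(ens, target_fn = function(x) 3 * x)
  expect_equal(d3, 3 * d, tolerance = 1e-9, ignore_attr = TRUE)

  # >= 50 neurons: identity RMS within 2% of the radius
  ens50 <- build_ensemble(ensemble_spec(50, 1, seed = 9))
  d50 <- solve_decoders(ens50)
  expect_lt(attr(d50, "rmse"), 0.02)
})

test_that("solved decoders beat randomly perturbed ones", {
  ens <- build_ensemble(ensemble_spec(30, 1, seed = 5))
  xs <- seq(-1, 1, length.out = 300)
  A <- ensemble_rates(ens, xs)
  d <- solve_decoders(ens, eval_points = xs, regularization = 0)
  base <- mean((A %*% d - xs)^2)
  set.seed(17)
  for (i in 1:20) {
    dp <- d + rnorm(length(d), sd = 0.1 * max(abs(d)))
    expect_gte(mean((A %*% dp - xs)^2), base)
  }
})

test_that("time-averaged spiking decode matches the rate-mode oracle", {
  ens <- build_ensemble(ensemble_spec(100, 1, seed = 3))
  d <- solve_decoders(ens)
  for (x0 in c(0, 0.5)) {
    sim <- simulate_spiking(ens, d, x0, T = 1)
    expect_equal(sim$mean, decode_rate(ens, d, x0), tolerance = 0.05)
  }
  expect_error(simulate_spiking(ens, d, 0, synapse = synapse_spec(tau = 0.005, dt = 0.01)),
               "dt must not exceed")
})

test_that("decoded variance shrinks as the population grows", {
  # Monte-Carlo over seeds: dispersion of the time-averaged decode of a
  # constant should not grow when neuron count quadruples
  err_for <- function(n, seeds) {
    vapply(seeds, function(s) {
      ens <- build_ensemble(ensemble_spec(n, 1, seed = s))
      d <- solve_decoders(ens)
      sim <- simulate_spiking(ens, d, 0.5, T = 0.3)
      abs(sim$mean - 0.5)
    }, numeric(1))
  }
  e_small <- err_for(10L, 1:20)
  e_large <- err_for(40L, 1:20)
  expect_lt(median(e_large), median(e_small))
})

test_that("spiking/rate consistency holds within the predicted noise band over seeds", {
  for (s in 1:10) {
    ens <- build_ensemble(ensemble_spec(100, 1, seed = s))
    d <- solve_decoders(ens)
    sim <- simulate_spiking(ens, d, 0.5, T = 0.5)
    band <- max(3 * sim$se, 0.01)
    expect_lt(abs(sim$mean - decode_rate(ens, d, 0.5)), band)
  }
})

test_that("recurrent dynamics realize a first-order lag and stay bounded at null", {
  # dx/dt = -x/tau_c + u settles at tau_c * u (distortion is amplified by
  # the loop gain tau_c/tau_syn, hence the tolerance)
  tau_c <- 0.1; u <- 2
  r <- simulate_recurrent(ensemble_spec(100, 1, seed = 5),
                          f = function(x) -x / tau_c, u = u, T = 1)
  expect_lt(abs(r$final - tau_c * u), 0.05)

  # null dynamics is a spiking integrator: it drifts but must stay near zero
  # over a short horizon (no systematic divergence)
  r0 <- simulate_recurrent(ensemble_spec(100, 1, seed = 2),
                           f = function(x) 0 * x, u = 0, T = 0.1)
  expect_lt(max(abs(r0$trace)), 0.3)
})

test_that("an expansive linear recurrence triggers the stability warning", {
  A_bad <- matrix(5, 1, 1)     # dx/dt = 5x
  expect_warning(
    simulate_recurrent(ensemble_spec(20, 1, seed = 1), f = A_bad, T = 0.02),
    "unstable")
  A_ok <- matrix(-5, 1, 1)
  expect_no_warning(
    simulate_recurrent(ensemble_spec(20, 1, seed = 1), f = A_ok, T = 0.02))
})
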
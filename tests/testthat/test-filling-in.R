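test_that("zero source yields the zero surface in every backend", {
  z <- matrix(0, 12, 12)
  expect_equal(max(abs(fillin_iterative(fillin_problem(z), "snapshot",
                                        n_steps = 50)$surface)), 0)
  expect_equal(max(abs(fillin_direct(fillin_problem(z))$surface)), 0)
  expect_equal(max(abs(fillin_direct(fillin_problem(z, "neumann"))$surface)),
               0, tolerance = 1e-12)
})

test_that("the iteration recovers a zero-border plane from its Laplacian source", {
  X <- smooth_zero_border_plane(32)
  src <- conv2_replicate(X, laplacian_kernel())
  prob <- fillin_problem(src)
  it <- fillin_iterative(prob, "converge", tol = 1e-6)
  expect_true(it$converged)
  expect_lt(max(abs(it$surface - X)), 1e-3)

  dr <- fillin_direct(prob)
  expect_lt(max(abs(dr$surface - X)), 1e-9)
  expect_lt(dr$residual, 1e-9)
  expect_lt(max(abs(it$surface - dr$surface)), 1e-4)
})

test_that("iterative and direct backends agree on random sources, both boundaries", {
  set.seed(31)
  for (i in 1:5) {
    src <- matrix(rnorm(32 * 32, sd = 0.2), 32, 32)
    for (bnd in c("dirichlet", "neumann")) {
      prob <- fillin_problem(src, boundary = bnd)
      it <- fillin_iterative(prob, "converge", tol = 1e-6)
      dr <- fillin_direct(prob)
      expect_lt(max(abs(it$surface - dr$surface)), 1e-4)
    }
  }
})

test_that("the iteration is linear in the source at equal step counts", {
  set.seed(8)
  s1 <- matrix(rnorm(100), 10, 10)
  s2 <- matrix(rnorm(100), 10, 10)
  f <- function(s) fillin_iterative(fillin_problem(s), "snapshot",
                                    n_steps = 40)$surface
  expect_equal(f(s1 + s2), f(s1) + f(s2), tolerance = 1e-10)
})

test_that("direct solve of a centred impulse is 4-fold symmetric; neumann case is flagged", {
  src <- matrix(0, 17, 17); src[9, 9] <- 1
  s <- fillin_direct(fillin_problem(src))$surface
  expect_equal(s, s[17:1, ], tolerance = 1e-12)
  expect_equal(s, t(s), tolerance = 1e-12)

  n <- fillin_direct(fillin_problem(src, "neumann"))
  expect_true(n$singular_grounded)
  expect_equal(mean(n$surface), 0, tolerance = 1e-12)
})

test_that("problem validation guards tau and finiteness", {
  expect_warning(fillin_problem(matrix(0, 4, 4), tau = 0.3), "unstable")
  expect_error(fillin_problem(matrix(c(NA, 0, 0, 0), 2, 2)), "non-finite")
})

test_that("snapshot filling is monotone at the centre and stable at tau = 0.25", {
  sq <- red_square_stimulus(side = 20, canvas = 50,
                            background = c(0, 0, 0))
  src <- double_opponent(rgb_to_opponent(sq))$do_rg
  prob <- fillin_problem(src)
  centers <- vapply(c(10, 50, 100, 200, 400), function(k)
    fillin_iterative(prob, "snapshot", n_steps = k)$surface[25, 25], numeric(1))
  expect_true(all(diff(centers) >= -1e-12))

  long <- fillin_iterative(prob, "snapshot", n_steps = 2000)
  expect_lt(max(abs(long$surface)), 10) # bounded, no divergence
})

test_that("fill ratio distinguishes filled, hollow, and constant surfaces", {
  mask <- matrix(FALSE, 30, 30); mask[8:23, 8:23] <- TRUE

  expect_equal(fill_ratio(matrix(1, 30, 30), mask), 1)

  hollow <- matrix(0, 30, 30)
  band <- mask & !chromafill:::erode_mask(chromafill:::erode_mask(mask))
  hollow[band] <- 1
  expect_equal(fill_ratio(hollow, mask), 0)

  # converged solution of a small square is fully filled
  sq <- make_square(5, canvas = c(30, 30), fill_rgb = c(1, 0, 0),
                    background_rgb = c(0, 0, 0))
  src <- double_opponent(rgb_to_opponent(sq))$do_rg
  conv <- fillin_iterative(fillin_problem(src), "converge", tol = 1e-6)
  expect_gte(fill_ratio(conv, attr(sq, "mask")), 0.8)

  expect_error(fill_ratio(matrix(0, 5, 5), matrix(FALSE, 5, 5)), "empty mask")
})

test_that("spiking backend approximates the converged surface and handles zero input", {
  sq <- make_square(6, canvas = c(16, 16), fill_rgb = c(1, 0, 0),
                    background_rgb = c(0, 0, 0))
  src <- double_opponent(rgb_to_opponent(sq))$do_rg
  prob <- fillin_problem(src)
  ref <- fillin_iterative(prob, "converge", tol = 1e-6)
  snn <- fillin_snn(prob, ensemble_spec(20, 0.6, seed = 1), run_time = 1)
  rmse <- sqrt(mean((snn$surface - ref$surface)^2))
  expect_lt(rmse / diff(range(ref$surface)), 0.05)

  z <- fillin_snn(fillin_problem(matrix(0, 8, 8)),
                  ensemble_spec(20, 0.6, seed = 1), run_time = 0.3)
  expect_lt(max(abs(z$surface)), 0.05)

  expect_warning(
    fillin_snn(fillin_problem(matrix(0, 4, 4)), ensemble_spec(10, 0.6, seed = 1),
               run_time = 0.02),
    "synaptic time constants")
})

test_that("spiking backend is reproducible from its seed", {
  src <- matrix(0, 8, 8); src[4, 4] <- 0.5
  prob <- fillin_problem(src)
  a <- fillin_snn(prob, ensemble_spec(10, 0.6, seed = 7), run_time = 0.2)
  b <- fillin_snn(prob, ensemble_spec(10, 0.6, seed = 7), run_time = 0.2)
  expect_identical(a$surface, b$surface)
})
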
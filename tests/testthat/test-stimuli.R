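test_that("square stimuli have exact pixel counts and opponent signature", {
  sq <- make_square(5, canvas = c(90, 90), fill_rgb = c(1, 0, 0),
                    background_rgb = c(0, 0, 0))
  mask <- attr(sq, "mask")
  expect_equal(sum(mask), 25L)
  expect_equal(sum(sq[, , 1] == 1), 25L)

  flat <- make_square(10, canvas = c(20, 20), fill_rgb = c(0.3, 0.3, 0.3),
                      background_rgb = c(0.3, 0.3, 0.3))
  expect_equal(max(flat) - min(flat), 0)

  # red on gray: RG plane positive inside, zero outside
  red <- red_square_stimulus(side = 10, canvas = 30)
  opp <- rgb_to_opponent(red)
  m <- attr(red, "mask")
  expect_true(all(opp$rg[m] > 0))
  expect_equal(max(abs(opp$rg[!m])), 0)

  expect_error(make_square(50, canvas = c(30, 30)), "does not fit")
})

test_that("assimilation grid covers width/step of the canvas and collapses at ratio 0", {
  src <- make_mondrian(c(512, 512), seed = 2)
  g <- make_assimilation_grid(src, step = 15, line_width = 3)
  cover <- mean(attr(g, "grid_mask"))
  expect_lt(abs(cover - 3 / 15) / (3 / 15), 0.02)

  g0 <- make_assimilation_grid(make_mondrian(c(60, 60), seed = 3),
                               step = 15, saturation_ratio = 0, clip = FALSE)
  expect_equal(g0, attr(g0, "base"), ignore_attr = TRUE, tolerance = 1e-12)

  # denser grids color strictly more pixels
  src2 <- make_mondrian(c(90, 90), seed = 4)
  g15 <- make_assimilation_grid(src2, step = 15)
  g50 <- make_assimilation_grid(src2, step = 50)
  expect_gt(sum(attr(g15, "grid_mask")), sum(attr(g50, "grid_mask")))

  expect_error(make_assimilation_grid(src2, step = 3, line_width = 3),
               "must exceed")
})

test_that("off-grid pixels are exactly the achromatic base", {
  src <- make_mondrian(c(48, 48), seed = 6)
  g <- make_assimilation_grid(src, step = 12)
  mask <- attr(g, "grid_mask")
  base <- attr(g, "base")
  for (ch in 1:3) {
    plane <- g[, , ch]; bp <- base[, , ch]
    expect_equal(plane[!mask], clip01(bp)[!mask], tolerance = 1e-12)
  }
  # the base is achromatic: zero chromatic opponent channels
  ob <- rgb_to_opponent(base)
  expect_lt(max(abs(ob$rg)), 1e-12)
  expect_lt(max(abs(ob$by)), 1e-12)
})

test_that("illumination tint interpolates with identity and shifts the BY channel", {
  img <- make_mondrian(c(32, 32), seed = 8)
  expect_equal(apply_illumination(img, c(0.9, 0.8, 0.2), strength = 0), img)
  expect_equal(apply_illumination(img, c(1, 1, 1), strength = 0.8), img)

  yellow <- apply_illumination(img, c(1, 0.9, 0.3), strength = 0.8)
  # yellow illumination raises R,G relative to B: mean BY moves positive
  expect_gt(mean(rgb_to_opponent(yellow)$by), mean(rgb_to_opponent(img)$by))
})

test_that("profile extraction averages, smooths, and respects bounds", {
  const <- matrix(0.7, 40, 60)
  p <- extract_profile(const, profile_cut("row", 20))
  expect_equal(p, rep(0.7, 60), tolerance = 1e-12)

  sq <- make_square(15, canvas = c(41, 41), fill_rgb = c(1, 0, 0),
                    background_rgb = c(0, 0, 0))
  plane <- rgb_to_opponent(sq)$rg
  prof <- extract_profile(plane, profile_cut("row", 21))
  expect_equal(prof, rev(prof), tolerance = 1e-10)   # symmetric about midline

  raw <- extract_profile(plane, profile_cut("row", 21, smoothing_sigma = 0))
  expect_equal(raw, colMeans(plane[19:23, ]), tolerance = 1e-12)

  expect_error(extract_profile(const, profile_cut("row", 1)), "outside image")
})

test_that("profile regression is affine-invariant and flags degenerate input", {
  set.seed(12)
  prof <- sin(seq(0, 3 * pi, length.out = 80)) + seq(0, 1, length.out = 80)
  self <- compare_profiles(prof, prof)
  expect_equal(self$r_squared, 1)
  aff <- compare_profiles(prof, -2.5 * prof + 0.3)
  expect_equal(aff$r_squared, 1)
  expect_lt(aff$p_value, 1e-10)

  flat <- compare_profiles(rep(1, 50), rnorm(50))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r_squared))

  # edge-anchored alignment: shifted copy realigned to R^2 = 1
  shifted <- c(rep(prof[1], 7), prof)[1:80]
  al <- compare_profiles(prof, shifted, sim_edges = c(20, 60),
                         ref_edges = c(27, 67))
  expect_gt(al$r_squared, 0.999)
})

test_that("a profile carries no information about independent noise", {
  set.seed(99)
  prof <- sin(seq(0, 2 * pi, length.out = 100))
  r2 <- vapply(1:100, function(i)
    compare_profiles(prof, rnorm(100))$r_squared, numeric(1))
  expect_gt(mean(r2 < 0.1), 0.9)
  expect_lt(median(r2), 0.05)
})
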
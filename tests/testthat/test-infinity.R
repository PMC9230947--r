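test_that("curve points follow x = cos(t), y = sin(alpha t)/beta", {
  ps <- generate_infinity_points(infinity_config(c = 1, n = 5))
  # t = 0, pi/4, pi/2, 3pi/4, pi
  expect_equal(ps$x[1], 1)
  expect_equal(ps$y[1], 0)
  expect_equal(ps$x[2], cos(pi / 4), tolerance = 1e-12)
  expect_equal(ps$y[2], 0.5, tolerance = 1e-12)  # sin(pi/2)/2
  expect_equal(ps$x[2], 0.70711, tolerance = 1e-5)
})

test_that("defaults trace 10 rounds with 5 points per round on average", {
  ps <- generate_infinity_points()
  expect_equal(nrow(ps), 50)
  expect_equal(max(ps$t), 20 * pi)
  rounds <- max(ps$t) / (2 * pi)
  expect_equal(rounds, 10)
  expect_equal(nrow(ps) / rounds, 5)
})

test_that("inclusive sampling drifts between rounds; algorithm1 repeats", {
  ps <- generate_infinity_points()
  # corresponding points one round apart never coincide
  for (i in seq_len(nrow(ps) - 5)) {
    expect_gt((ps$x[i] - ps$x[i + 5])^2 + (ps$y[i] - ps$y[i + 5])^2, 1e-12)
  }
  alg <- generate_infinity_points(infinity_config(sampling = "algorithm1"))
  expect_equal(nrow(alg), 51)
  for (i in seq_len(nrow(alg) - 5)) {
    expect_equal(alg$x[i], alg$x[i + 5], tolerance = 1e-9)
    expect_equal(alg$y[i], alg$y[i + 5], tolerance = 1e-9)
  }
})

test_that("full-domain sampling closed under half-period shift is symmetric", {
  # negation (x, y) -> (-x, -y) corresponds to t -> t + pi; the inclusive
  # grid contains that shift exactly when (n - 1) is a multiple of c
  for (cfg in list(infinity_config(c = 2, n = 9),
                   infinity_config(c = 20, n = 41))) {
    ps <- generate_infinity_points(cfg)
    ps <- ps[-nrow(ps), ]  # final point repeats t = 0 (whole cos-periods)
    a <- ps[order(round(ps$x, 9), round(ps$y, 9)), c("x", "y")]
    b <- ps[order(round(-ps$x, 9), round(-ps$y, 9)), c("x", "y")]
    expect_equal(a$x, -b$x, tolerance = 1e-9)
    expect_equal(a$y, -b$y, tolerance = 1e-9)
  }
})

test_that("normalization maps endpoints and midpoints and inverts cleanly", {
  ps <- generate_infinity_points()
  n1 <- normalize_points(ps,
                         norm_range(min(ps$x), max(ps$x), 0, 99),
                         norm_range(min(ps$y), max(ps$y), 0, 45))
  expect_equal(min(n1$x), 0)
  expect_equal(max(n1$x), 99)
  mid <- normalize_points(ps, norm_range(-1, 1, 0, 100), norm_range(-1, 1, 0, 100))
  expect_equal(mid$x[1], 100)  # x = cos(0) = 1 -> top of range
  expect_equal(mid$y[1], 50)   # y = 0, the source midpoint -> 50
  # round trip through the inverse map
  back <- normalize_points(n1,
                           norm_range(0, 99, min(ps$x), max(ps$x)),
                           norm_range(0, 45, min(ps$y), max(ps$y)))
  expect_equal(back$x, ps$x, tolerance = 1e-9)
  expect_equal(back$y, ps$y, tolerance = 1e-9)
  expect_error(normalize_points(ps, norm_range(1, 1, 0, 9), norm_range(0, 1, 0, 9)),
               "degenerate")
  expect_equal(nrow(n1), nrow(ps))
})

test_that("placement anchors the centroid at the seed and stays in bounds", {
  # shape smaller than the frame, so the border never constrains the shift
  ps <- generate_infinity_points() |> normalize_to_image(60, 20)
  placed <- place_at_seed(ps, list(x = 50, y = 20), 100, 40)
  expect_equal(nrow(placed), nrow(ps))
  expect_true(all(placed$x >= 1 & placed$x <= 100))
  expect_true(all(placed$y >= 1 & placed$y <= 40))
  # centroid lands on the seed up to rounding when unconstrained
  expect_lt(abs(mean(placed$x) - 50), 1)
  expect_lt(abs(mean(placed$y) - 20), 1)

  # seed at a corner: the shape is shifted as a whole, not clipped pointwise
  corner <- place_at_seed(ps, list(x = 1, y = 1), 100, 40)
  expect_gt(mean(corner$x), 25)  # centroid pulled back inside, not clipped
  expect_true(all(corner$x >= 1 & corner$x <= 100))
  expect_lte(abs(diff(range(corner$x)) - diff(range(placed$x))), 1)

  big <- generate_infinity_points() |> normalize_to_image(500, 300)
  expect_error(place_at_seed(big, list(x = 10, y = 10), 100, 40), "larger")
})

test_that("small canvas profile works end to end", {
  f <- generate_upper_face(synthetic_face_spec(profile = "small", rng_seed = 2))
  expect_equal(dim(f$image), c(46, 100))
  placed <- placed_curve(f$image)
  lms <- detect_landmarks(f$image, placed)
  expect_gt(nrow(lms), 0)
})
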
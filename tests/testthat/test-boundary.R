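test_that("segment rasterization is exact on axis lines and degenerate points", {
  h <- rasterize_segment(c(1, 1), c(4, 1))
  expect_equal(h$x, 1:4)
  expect_equal(h$y, rep(1, 4))
  pt <- rasterize_segment(c(3, 5), c(3, 5))
  expect_equal(nrow(pt), 1)
  expect_equal(c(pt$x, pt$y), c(3, 5))
})

test_that("rasterization reverses exactly and stays on the ideal line", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      p0 <- c(sample(40, 1), sample(40, 1))
      p1 <- c(sample(40, 1), sample(40, 1))
      fwd <- rasterize_segment(p0, p1)
      bwd <- rasterize_segment(p1, p0)
      expect_equal(fwd$x, rev(bwd$x))
      expect_equal(fwd$y, rev(bwd$y))
      # endpoints included; 8-connected steps; within half a pixel of the line
      expect_equal(c(fwd$x[1], fwd$y[1]), p0)
      expect_equal(c(fwd$x[nrow(fwd)], fwd$y[nrow(fwd)]), p1)
      expect_true(all(pmax(abs(diff(fwd$x)), abs(diff(fwd$y))) == 1))
      expect_lte(max(oracle_line_distance(fwd$x, fwd$y, p0, p1)), 0.5 + 1e-9)
      # same pixel count as the DDA reference
      expect_equal(nrow(fwd), nrow(oracle_dda_line(p0, p1)))
    }
  })
})

test_that("profiles concatenate two segments sharing the midpoint once", {
  img <- matrix(seq_len(20 * 30) %% 251, 20, 30)
  triple <- tibble::tibble(x = c(2, 10, 25), y = c(3, 3, 3))
  prof <- extract_profile(img, triple)
  expect_equal(prof$value, as.numeric(img[3, 2:25]))  # collinear row run
  seg1 <- rasterize_segment(c(2, 3), c(10, 3))
  seg2 <- rasterize_segment(c(10, 3), c(25, 3))
  expect_equal(nrow(prof), nrow(seg1) + nrow(seg2) - 1)
  const <- extract_profile(matrix(9, 20, 30), triple)
  expect_true(all(const$value == 9))
  expect_error(extract_profile(img, tibble::tibble(x = c(2, 10, 99), y = c(3, 3, 3))),
               "outside")
})

test_that("single spikes and monotone profiles behave as defined", {
  pk <- find_profile_peaks(c(0, 5, 0))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apex, 2)
  expect_equal(pk$prominence, 5)
  expect_equal(pk$left_base, 1)
  expect_equal(nrow(find_profile_peaks(1:10)), 0)
  expect_equal(nrow(find_profile_peaks(10:1)), 0)
  expect_equal(nrow(find_profile_peaks(c(1, 2))), 0)
})

test_that("peak analysis agrees with the brute-force oracle on random profiles", {
  withr::with_seed(21, {
    for (rep in 1:200) {
      n <- sample(3:64, 1)
      x <- if (rep %% 2 == 0) {
        round(runif(n, 0, 255))          # plateau-heavy integer profiles
      } else {
        runif(n, 0, 255)
      }
      expect_same_peaks(x, info = paste("profile", rep))
    }
  })
})

test_that("landmark detection respects thresholds, traces, and polarity", {
  expect_equal(nrow(detect_landmarks(matrix(100, 50, 100),
                                     placed_curve(matrix(100, 50, 100)))), 0)

  f <- default_face(seed = 6)
  placed <- placed_curve(f$image)
  lms <- detect_landmarks(f$image, placed)
  expect_gt(nrow(lms), 0)
  expect_false(any(duplicated(lms[, c("x", "y")])))

  # all landmarks lie on the union of rasterized traces
  trace <- dplyr::bind_rows(lapply(seq_len(nrow(placed) - 2), function(i) {
    extract_profile(f$image, placed[i:(i + 2), ])[, c("x", "y")]
  }))
  expect_true(all(paste(lms$x, lms$y) %in% paste(trace$x, trace$y)))

  # landmark count is monotone non-increasing in both thresholds
  proms <- c(10, 40, 76.5, 120, 200)
  counts <- vapply(proms, function(p) {
    nrow(detect_landmarks(f$image, placed, min_prominence = p))
  }, double(1))
  expect_true(all(diff(counts) <= 0))
  widths <- c(1, 3, 6, 12)
  counts_w <- vapply(widths, function(w) {
    nrow(detect_landmarks(f$image, placed, min_width = w))
  }, double(1))
  expect_true(all(diff(counts_w) <= 0))

  # intensity-inversion duality: valley detection on the negative image
  # reproduces the bright-peak landmarks exactly
  inv <- 255 - f$image
  lms_inv <- detect_landmarks(inv, placed, invert = TRUE)
  expect_equal(lms_inv$x, lms$x)
  expect_equal(lms_inv$y, lms$y)
  expect_equal(lms_inv$prominence, lms$prominence)

  expect_error(detect_landmarks(f$image, placed[1:2, ]), "at least 3")
})

test_that("landmarks recover the true boundaries on default fixtures", {
  hits <- vapply(1:10, function(k) {
    f <- default_face(seed = 300 + k)
    lms <- detect_landmarks(f$image, placed_curve(f$image))
    mean(boundary_distances(lms, f$boundary_mask) <= 3)
  }, double(1))
  expect_gte(mean(hits), 0.7)
})
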
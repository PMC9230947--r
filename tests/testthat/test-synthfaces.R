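test_that("rendering is deterministic and honours the stated contrasts", {
  sp <- synthetic_face_spec(rng_seed = 42)
  f1 <- generate_upper_face(sp)
  f2 <- generate_upper_face(sp)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$boundary_mask, f2$boundary_mask)
  expect_equal(dim(f1$image), c(96, 236))

  cm <- colMeans(f1$image)
  expect_gt(cm[sp$nose_col], max(cm[-sp$nose_col]))

  # contrast contract: darkest eye pixel well under the background
  eye <- f1$image[facemark:::ellipse_mask(sp$width, sp$height,
                                          sp$eye_centers[1, 1], sp$eye_centers[1, 2],
                                          sp$eye_radii[1, 1], sp$eye_radii[1, 2])]
  expect_lt(min(eye), sp$background_level - 2 * sp$noise_sd)

  expect_equal(f1$true_seed$x, sp$nose_col)
  expect_true(f1$true_seed$y > 1 && f1$true_seed$y < sp$height)
})

test_that("boundary mask pixels trace the rendered feature outlines", {
  f <- default_face(seed = 8, noise_sd = 0)
  sp <- f$spec
  bm <- which(f$boundary_mask, arr.ind = TRUE)
  expect_gt(nrow(bm), 0)
  # every mask pixel sits within 1 px of an eye ellipse or a brow band edge
  on_outline <- vapply(seq_len(nrow(bm)), function(i) {
    x <- bm[i, 2]; y <- bm[i, 1]
    for (e in 1:2) {
      v <- ((x - sp$eye_centers[e, 1]) / sp$eye_radii[e, 1])^2 +
        ((y - sp$eye_centers[e, 2]) / sp$eye_radii[e, 2])^2
      if (abs(sqrt(v) - 1) * min(sp$eye_radii[e, ]) < 2) return(TRUE)
    }
    for (b in 1:2) {
      ba <- sp$brow_arcs[b, ]
      u <- (x - ba$cx) / ba$radius
      if (abs(u) > 1.05) next
      ytop <- ba$cy - ba$arch * (1 - min(u^2, 1))
      if (y > ytop - 2 && y < ytop + ba$thickness + 2) return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_true(all(on_outline))
})

test_that("invalid geometry and unknown classes are rejected", {
  expect_error(synthetic_face_spec(eye_centers = rbind(c(-5, 60), c(170, 60))),
               "invalid spec")
  expect_error(synthetic_face_spec(feature_level = 250),
               "darker than the background")
  expect_error(generate_dataset(1, c("neutral", "boredom")), "unknown class")
})

test_that("datasets are balanced and class deformations act as documented", {
  ds <- generate_dataset(2, c("neutral", "surprise"), rng_seed = 7)
  expect_length(ds, 4)
  expect_equal(sum(vapply(ds, `[[`, "", "label") == "neutral"), 2)
  expect_identical(
    generate_dataset(2, c("neutral", "surprise"), rng_seed = 7)[[1]]$image,
    ds[[1]]$image
  )

  big <- generate_dataset(50, c("neutral", "surprise"), rng_seed = 11)
  labs <- vapply(big, `[[`, "", "label")
  brow_row <- vapply(big, function(f) mean(f$spec$brow_arcs$cy), double(1))
  # surprise raises the brows: smaller row index than neutral
  expect_lt(mean(brow_row[labs == "surprise"]), mean(brow_row[labs == "neutral"]))

  # jitter seed changes samples but class-mean geometry stays put (~1 px)
  big2 <- generate_dataset(50, c("neutral", "surprise"), rng_seed = 12)
  brow_row2 <- vapply(big2, function(f) mean(f$spec$brow_arcs$cy), double(1))
  labs2 <- vapply(big2, `[[`, "", "label")
  for (cl in c("neutral", "surprise")) {
    expect_lt(abs(mean(brow_row[labs == cl]) - mean(brow_row2[labs2 == cl])), 1)
  }
})

test_that("full faces embed the upper rendering and expose lower features", {
  sp <- synthetic_face_spec(rng_seed = 19)
  ff <- generate_full_face(sp)
  expect_s3_class(ff$box, "face_box")
  # upper crop reproduces the upper-face rendering pixel for pixel
  crop <- crop_upper_face(ff$image, ff$box, 0.42)
  expect_equal(dim(crop), dim(ff$upper$image))
  expect_true(all(crop == ff$upper$image))
  # the lower polygon covers every lower-region feature pixel
  feats <- which(ff$lower_feature_mask, arr.ind = TRUE)
  expect_true(all(feats[, 1] >= min(ff$lower_polygon[, "y"])))
  expect_true(all(feats[, 1] <= max(ff$lower_polygon[, "y"])))
})

test_that("fixture writing produces readable PNGs and a manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(1, c("neutral", "anger"), rng_seed = 3)
  man <- write_fixtures(ds, dir)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$path)))
  back <- read_image(man$path[1])
  expect_identical(back, ds[[1]]$image)
})
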
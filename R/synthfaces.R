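#' Specification of a synthetic upper face
#'
#' Describes the rendered geometry of a synthetic upper-face crop: a light
#' skin background, a bright vertical nose-bridge band, two dark elliptical
#' eye regions with a slightly darker rim (the lash/lid line, which is
#' where real eyes are darkest), and two dark eyebrow arcs. The default
#' canvas is 236 x 96, the average upper-face crop size of frontal
#' lab-posed portraits; `profile = "small"` gives the 100 x 46 in-the-wild
#' equivalent. Per-emotion deformations (brow raise/lower, eye
#' opening/squint) are applied by [generate_dataset()].
#'
#' @param width,height Canvas size in pixels.
#' @param nose_col Column of the nose-bridge band centre.
#' @param eye_centers Two-row matrix (or 2-element list of `c(x, y)`) of
#'   eye centres.
#' @param eye_radii Two-row matrix of per-eye `(rx, ry)` semi-axes.
#' @param brow_arcs Two-row data frame with columns `cx`, `cy` (arc base),
#'   `radius` (half-width), `thickness`, `arch` (vertical offset of the
#'   arc apex above its base).
#' @param background_level,feature_level 8-bit skin and dark-feature
#'   intensities; features must be darker than skin.
#' @param eye_level,brow_level Optional per-feature overrides of
#'   `feature_level` (used by the three contrast regimes).
#' @param regime Contrast regime of the eye/brow bands: `"blended"`
#'   (similar darkness), `"eye_darker"`, or `"brow_darker"`.
#' @param noise_sd Additive Gaussian pixel noise, in intensity units.
#' @param class_label Emotion label carried through to the fixture.
#' @param rng_seed Integer seed making the rendering reproducible.
#' @param profile `"ck"` (236 x 96 canvas) or `"small"` (100 x 46);
#'   geometry defaults scale with the canvas.
#' @return A list of class `synthetic_face_spec`.
#' @export
synthetic_face_spec <- function(width = NULL, height = NULL,
                                nose_col = NULL,
                                eye_centers = NULL, eye_radii = NULL,
                                brow_arcs = NULL,
                                background_level = 180, feature_level = 60,
                                eye_level = NULL, brow_level = NULL,
                                regime = c("blended", "eye_darker", "brow_darker"),
                                noise_sd = 4, class_label = "neutral",
                                rng_seed = 1L,
                                profile = c("ck", "small")) {
  profile <- match.arg(profile)
  regime <- match.arg(regime)
  if (is.null(width)) width <- if (profile == "ck") 236L else 100L
  if (is.null(height)) height <- if (profile == "ck") 96L else 46L
  w <- as.integer(width)
  h <- as.integer(height)
  if (is.null(nose_col)) nose_col <- round(w / 2)
  if (is.null(eye_centers)) {
    eye_centers <- rbind(
      c(round(0.28 * w), round(0.62 * h)),
      c(round(0.72 * w), round(0.62 * h))
    )
  }
  eye_centers <- as_two_row(eye_centers)
  if (is.null(eye_radii)) {
    r <- c(round(0.095 * w), max(3, round(0.07 * h)))
    eye_radii <- rbind(r, r)
  }
  eye_radii <- as_two_row(eye_radii)
  if (is.null(brow_arcs)) {
    brow_arcs <- tibble::tibble(
      cx = eye_centers[, 1],
      cy = round(0.36 * h),
      radius = round(0.11 * w),
      thickness = max(3, round(0.04 * h)),
      arch = max(3, round(0.06 * h))
    )
  }
  lv <- regime_levels(regime, feature_level)
  spec <- structure(list(
    width = w, height = h, nose_col = as.integer(nose_col),
    eye_centers = eye_centers, eye_radii = eye_radii,
    brow_arcs = tibble::as_tibble(brow_arcs),
    background_level = background_level, feature_level = feature_level,
    eye_level = eye_level %||% lv$eye, brow_level = brow_level %||% lv$brow,
    regime = regime, noise_sd = noise_sd,
    class_label = class_label, rng_seed = as.integer(rng_seed)
  ), class = "synthetic_face_spec")
  validate_face_spec(spec)
}

regime_levels <- function(regime, feature_level) {
  switch(regime,
    blended     = list(eye = feature_level, brow = feature_level - 2),
    eye_darker  = list(eye = feature_level - 15, brow = feature_level + 25),
    brow_darker = list(eye = feature_level + 25, brow = feature_level - 15)
  )
}

as_two_row <- function(x) {
  m <- if (is.list(x) && !is.data.frame(x)) do.call(rbind, x) else as.matrix(x)
  if (!all(dim(m) == c(2, 2))) abort("expected two (x, y) or (rx, ry) pairs")
  unname(m)
}

validate_face_spec <- function(spec) {
  with(spec, {
    if (background_level < 0 || background_level > 255 ||
        eye_level < 0 || brow_level < 0 || eye_level > 255 || brow_level > 255) {
      abort("intensity levels must lie in [0, 255]")
    }
    if (max(eye_level, brow_level) >= background_level) {
      abort("features must be darker than the background (invalid spec)")
    }
    if (noise_sd < 0) abort("noise_sd must be >= 0")
    inside <- eye_centers[, 1] - eye_radii[, 1] >= 1 &
      eye_centers[, 1] + eye_radii[, 1] <= width &
      eye_centers[, 2] - eye_radii[, 2] >= 1 &
      eye_centers[, 2] + eye_radii[, 2] <= height
    if (!all(inside)) abort("eye geometry falls outside the image (invalid spec)")
    if (nose_col < 1 || nose_col > width) abort("nose_col outside image (invalid spec)")
    if (any(brow_arcs$cy - brow_arcs$arch < 1) ||
        any(brow_arcs$cy + brow_arcs$thickness > height)) {
      abort("brow geometry falls outside the image (invalid spec)")
    }
  })
  spec
}

# Filled-ellipse pixel mask on a h x w grid.
ellipse_mask <- function(w, h, cx, cy, rx, ry) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
}

# Eyebrow band: thickness-deep band under the arched curve
# y(x) = cy - arch * (1 - ((x - cx)/radius)^2), |x - cx| <= radius.
brow_mask <- function(w, h, cx, cy, radius, thickness, arch) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  u <- (xs - cx) / radius
  ytop <- cy - arch * (1 - u^2)
  abs(u) <= 1 & ys >= ytop & ys < ytop + thickness
}

# 4-neighbour boundary of a logical region.
region_boundary <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-h, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -w, drop = FALSE])
  m & !(up & dn & lf & rt)
}

# Run code under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Render a synthetic upper face with ground truth
#'
#' Deterministically renders the face described by `spec` and returns the
#' image together with its ground truth: a binary mask of the true
#' eye/eyebrow boundary pixels, the true seed point (nose column x
#' midpoint between the brow and eye rows), and the class label.
#'
#' @param spec A [synthetic_face_spec()].
#' @return A list of class `synthetic_upper_face` with elements `image`,
#'   `boundary_mask`, `true_seed` (one-row tibble `x`, `y`), `label`,
#'   `spec`.
#' @export
#' @examples
#' face <- generate_upper_face(synthetic_face_spec(rng_seed = 42))
#' dim(face$image)
generate_upper_face <- function(spec) {
  stopifnot(inherits(spec, "synthetic_face_spec"))
  w <- spec$width
  h <- spec$height
  img <- matrix(spec$background_level, h, w)

  # bright nose-bridge highlight: peaked at nose_col with Gaussian falloff,
  # so the brightest column is unambiguous (specular ridge, not a flat stripe)
  sigma <- max(2, 0.015 * w)
  boost <- 50 * exp(-((seq_len(w) - spec$nose_col) / sigma)^2)
  boost[boost < 1] <- 0
  img <- pmin(img + matrix(boost, h, w, byrow = TRUE), 255)

  boundary <- matrix(FALSE, h, w)
  rim_drop <- 25
  for (e in 1:2) {
    cx <- spec$eye_centers[e, 1]
    cy <- spec$eye_centers[e, 2]
    rx <- spec$eye_radii[e, 1]
    ry <- spec$eye_radii[e, 2]
    eye <- ellipse_mask(w, h, cx, cy, rx, ry)
    inner <- ellipse_mask(w, h, cx, cy, max(rx - 1.5, 1), max(ry - 1.5, 1))
    img[eye] <- spec$eye_level
    img[eye & !inner] <- max(0, spec$eye_level - rim_drop)  # dark lash/lid rim
    boundary <- boundary | region_boundary(eye)
  }
  for (b in 1:2) {
    ba <- spec$brow_arcs[b, ]
    brow <- brow_mask(w, h, ba$cx, ba$cy, ba$radius, ba$thickness, ba$arch)
    img[brow] <- spec$brow_level
    boundary <- boundary | region_boundary(brow)
  }

  if (spec$noise_sd > 0) {
    img <- with_seed(spec$rng_seed, img + rnorm(length(img), 0, spec$noise_sd))
  }
  img <- clip8(img)

  brow_mid <- mean(spec$brow_arcs$cy - spec$brow_arcs$arch / 2 +
                     spec$brow_arcs$thickness / 2)
  eye_mid <- mean(spec$eye_centers[, 2])
  structure(list(
    image = img,
    boundary_mask = boundary,
    true_seed = tibble::tibble(
      x = spec$nose_col,
      y = as.integer(round((brow_mid + eye_mid) / 2))
    ),
    label = spec$class_label,
    spec = spec
  ), class = "synthetic_upper_face")
}

# Fixed per-emotion deformation table (pixels on the 236 x 96 canvas,
# scaled by canvas height for other profiles): negative brow_dy raises.
emotion_deformations <- function() {
  tibble::tribble(
    ~class,      ~brow_dy, ~brow_asym, ~arch_d, ~eye_ry_d, ~eye_rx_d,
    "neutral",          0,          0,       0,         0,         0,
    "anger",            3,          0,      -4,        -1,         0,
    "contempt",         0,          4,      -1,        -1,         0,
    "disgust",          4,          0,      -2,        -2,         0,
    "fear",            -4,          0,       1,         2,         0,
    "happiness",       -1,          0,       0,        -2,         1,
    "sadness",          2,          0,      -3,        -1,         0,
    "surprise",        -7,          0,       2,         3,        -2
  )
}

#' Emotion classes understood by the generator
#' @return Character vector of the eight lab-posed emotion labels.
#' @export
emotion_classes <- function() emotion_deformations()$class

#' Generate a balanced labelled dataset of synthetic upper faces
#'
#' Applies a fixed per-class geometric deformation (e.g. surprise raises
#' the brows and widens the eyes; anger lowers and flattens them) plus
#' small within-class jitter (1 px s.d. on positions) to a base spec.
#'
#' @param n_per_class Faces per class (>= 1).
#' @param classes Subset of [emotion_classes()].
#' @param base_spec Base [synthetic_face_spec()]; class deformations and
#'   jitter perturb it.
#' @param rng_seed Seed controlling jitter and per-face rendering seeds.
#' @return A list of `synthetic_upper_face` objects, `n_per_class` per
#'   class, in class-major order.
#' @export
generate_dataset <- function(n_per_class, classes = emotion_classes(),
                             base_spec = synthetic_face_spec(),
                             rng_seed = 1L) {
  stopifnot(n_per_class >= 1, length(classes) >= 1)
  defs <- emotion_deformations()
  unknown <- setdiff(classes, defs$class)
  if (length(unknown)) {
    abort(sprintf("unknown class label(s): %s", paste(unknown, collapse = ", ")))
  }
  scale <- base_spec$height / 96
  with_seed(rng_seed, {
    out <- list()
    for (cl in classes) {
      d <- defs[defs$class == cl, ]
      for (i in seq_len(n_per_class)) {
        ba <- base_spec$brow_arcs
        ba$cy <- ba$cy + round(scale * (d$brow_dy + c(-1, 1) * d$brow_asym / 2)) +
          round(rnorm(2, 0, 1))
        ba$arch <- pmax(0, ba$arch + round(scale * d$arch_d))
        ec <- base_spec$eye_centers + matrix(round(rnorm(4, 0, 1)), 2, 2)
        er <- base_spec$eye_radii
        er[, 2] <- pmax(3, er[, 2] + round(scale * d$eye_ry_d))
        er[, 1] <- pmax(6, er[, 1] + round(scale * d$eye_rx_d))
        sp <- synthetic_face_spec(
          width = base_spec$width, height = base_spec$height,
          nose_col = base_spec$nose_col + round(rnorm(1, 0, 1)),
          eye_centers = ec, eye_radii = er, brow_arcs = ba,
          background_level = base_spec$background_level,
          feature_level = base_spec$feature_level,
          regime = base_spec$regime,
          noise_sd = base_spec$noise_sd,
          class_label = cl,
          rng_seed = sample.int(.Machine$integer.max - 1L, 1)
        )
        out[[length(out) + 1]] <- generate_upper_face(sp)
      }
    }
    out
  })
}

#' Generate a synthetic full face for mask-overlay tests
#'
#' Embeds the upper-face rendering in a taller canvas whose lower region
#' contains distinct dark mouth and nose-tip blobs that a synthetic mask
#' must hide, plus the face bounding box and a polygon covering the
#' lower-region features.
#'
#' @param spec A [synthetic_face_spec()] for the upper part.
#' @param rng_seed Seed for the lower-region noise.
#' @param upper_fraction Fraction of the full face height occupied by the
#'   upper crop (the upper rows reproduce [generate_upper_face()] exactly).
#' @return A list of class `synthetic_full_face`: `image`, `box` (a
#'   [face_box()]), `lower_polygon` (matrix of `(x, y)` vertices),
#'   `lower_feature_mask`, `upper` (the `synthetic_upper_face`).
#' @export
generate_full_face <- function(spec, rng_seed = spec$rng_seed,
                               upper_fraction = 0.42) {
  upper <- generate_upper_face(spec)
  w <- spec$width
  hu <- spec$height
  hf <- as.integer(round(hu / upper_fraction))
  img <- matrix(spec$background_level, hf, w)
  img[seq_len(hu), ] <- upper$image

  mouth <- ellipse_mask(w, hf, round(w / 2), round(0.82 * hf),
                        round(0.14 * w), round(0.045 * hf))
  nosetip <- ellipse_mask(w, hf, round(w / 2), round(0.60 * hf),
                          round(0.05 * w), round(0.035 * hf))
  img[nosetip] <- spec$feature_level + 30
  img[mouth] <- spec$feature_level - 10
  lower <- matrix(FALSE, hf, w)
  lower[(hu + 1):hf, ] <- TRUE
  if (spec$noise_sd > 0) {
    img[lower] <- with_seed(rng_seed + 1L,
      img[lower] + rnorm(sum(lower), 0, spec$noise_sd))
  }
  img <- clip8(img)

  ytop <- hu + 1
  poly <- cbind(x = c(1, w, w, 1), y = c(ytop, ytop, hf, hf))
  structure(list(
    image = img,
    box = face_box(1, 1, w, hf),
    lower_polygon = poly,
    lower_feature_mask = (mouth | nosetip) & lower,
    upper = upper
  ), class = "synthetic_full_face")
}

#' Write a generated dataset to disk as PNG fixtures with a manifest
#'
#' @param dataset List of `synthetic_upper_face` (from [generate_dataset()]).
#' @param dir Output directory (created if missing).
#' @return Tibble manifest (`path`, `mask_path`, `label`, `seed`),
#'   invisibly; also written to `manifest.csv` in `dir`.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::imap(dataset, function(f, i) {
    path <- file.path(dir, sprintf("face_%03d.png", i))
    mask_path <- file.path(dir, sprintf("face_%03d_mask.png", i))
    write_image(f$image, path)
    png::writePNG(f$boundary_mask * 1, mask_path)
    tibble::tibble(path = path, mask_path = mask_path,
                   label = f$label, seed = f$spec$rng_seed)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
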
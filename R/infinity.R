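#' Configuration of the infinity-shaped sampling curve
#'
#' The sampling path is the Lissajous figure `x = cos(t)`,
#' `y = sin(alpha * t) / beta` traced over `t` in `[0, c * pi]`. With the
#' defaults `alpha = 2`, `beta = 2`, `c = 20`, `n = 50` the curve is a
#' figure-eight traversed over 10 full cos-periods ("rounds") with on
#' average 5 points per round; because the `n` samples are spread
#' *inclusively* over the domain (step `c*pi/(n-1)`), the points of
#' consecutive rounds drift rather than repeat, so together they blanket
#' the eye/eyebrow region.
#'
#' @param alpha Number of circular-like lobes (vertical frequency).
#' @param beta Height divisor of the shape.
#' @param c Half-period count: `t` spans `[0, c*pi]`, i.e. `c/2` rounds.
#' @param n Number of sampled points (>= 4).
#' @param sampling `"inclusive"` (n points, step `c*pi/(n-1)`; default) or
#'   `"algorithm1"` (n+1 points at step `c*pi/n`, which makes every round
#'   retrace the same 5 positions).
#' @param height_ratio Fraction of the image height the normalized shape
#'   spans (see [normalize_to_image()]).
#' @return A list of class `infinity_config`.
#' @export
infinity_config <- function(alpha = 2, beta = 2, c = 20, n = 50,
                            sampling = c("inclusive", "algorithm1"),
                            height_ratio = 1.0) {
  sampling <- match.arg(sampling)
  stopifnot(alpha >= 1, beta > 0, c > 0, n >= 4, height_ratio > 0,
            height_ratio <= 1)
  structure(list(alpha = alpha, beta = beta, c = c, n = as.integer(n),
                 sampling = sampling, height_ratio = height_ratio),
            class = "infinity_config")
}

new_infinity_points <- function(df, config, frame) {
  out <- tibble::new_tibble(df, config = config, frame = frame,
                            class = "infinity_points")
  out
}

#' Generate the infinity-shaped point set
#'
#' @param config An [infinity_config()].
#' @return A tibble of class `infinity_points` with columns `t`, `x`, `y`
#'   in curve units (`|x| <= 1`, `|y| <= 1/beta`), ordered along the
#'   curve; attributes `config` and `frame = "unit"`.
#' @export
#' @examples
#' ps <- generate_infinity_points(infinity_config())
#' range(ps$x)
generate_infinity_points <- function(config = infinity_config()) {
  stopifnot(inherits(config, "infinity_config"))
  tmax <- config$c * pi
  t <- if (config$sampling == "inclusive") {
    seq(0, tmax, length.out = config$n)
  } else {
    seq(0, tmax, by = tmax / config$n)
  }
  new_infinity_points(
    tibble::tibble(t = t, x = cos(t), y = sin(config$alpha * t) / config$beta),
    config, "unit"
  )
}

#' Axis normalization range
#'
#' @param min_old,max_old Source range (must be non-degenerate).
#' @param min_new,max_new Target range.
#' @return A list of class `norm_range`.
#' @export
norm_range <- function(min_old, max_old, min_new, max_new) {
  if (max_old <= min_old) abort("degenerate source range: max_old <= min_old")
  if (max_new < min_new) abort("target range must satisfy max_new >= min_new")
  structure(list(min_old = min_old, max_old = max_old,
                 min_new = min_new, max_new = max_new),
            class = "norm_range")
}

affine_map <- function(v, r) {
  (v - r$min_old) / (r$max_old - r$min_old) * (r$max_new - r$min_new) + r$min_new
}

#' Rescale the point set per axis
#'
#' Affine per-axis map taking `min_old -> min_new` and `max_old ->
#' max_new` — used to blow the unit-frame curve up to the size of an
#' individual upper-face crop.
#'
#' @param points An `infinity_points` tibble.
#' @param rng_x,rng_y [norm_range()] objects for the x and y axes.
#' @return The rescaled `infinity_points`, frame `"normalized"`.
#' @export
normalize_points <- function(points, rng_x, rng_y) {
  stopifnot(inherits(points, "infinity_points"),
            inherits(rng_x, "norm_range"), inherits(rng_y, "norm_range"))
  df <- tibble::tibble(t = points$t,
                       x = affine_map(points$x, rng_x),
                       y = affine_map(points$y, rng_y))
  new_infinity_points(df, attr(points, "config"), "normalized")
}

#' Normalize the curve to the dimensions of an upper-face image
#'
#' Maps the observed x-range onto `[1, width]` and the observed y-range
#' onto a band of `height_ratio * (height - 1) + 1` rows, so the shape
#' spans the crop.
#'
#' @param points Unit-frame `infinity_points`.
#' @param width,height Upper-face image dimensions in pixels.
#' @param height_ratio Overrides the config's `height_ratio` if given.
#' @return Normalized `infinity_points`.
#' @export
normalize_to_image <- function(points, width, height, height_ratio = NULL) {
  cfg <- attr(points, "config")
  hr <- height_ratio %||% cfg$height_ratio
  normalize_points(
    points,
    norm_range(min(points$x), max(points$x), 1, width),
    norm_range(min(points$y), max(points$y), 1, 1 + round(hr * (height - 1)))
  )
}

#' Move the normalized shape to the seed point
#'
#' Translates the whole point set so its centroid lands on the seed
#' point; if that pushes the bounding box over an image border the
#' translation (not the individual points) is reduced until the box fits,
#' preserving the shape's geometry. Coordinates are then rounded to
#' integer pixels (half away from zero).
#'
#' @param points Normalized `infinity_points` (pixel units, no larger
#'   than the image).
#' @param seed Seed point: one-row data frame or named list with `x`, `y`.
#' @param image_w,image_h Image dimensions.
#' @return `infinity_points` with integer pixel coordinates, frame
#'   `"placed"`.
#' @export
place_at_seed <- function(points, seed, image_w, image_h) {
  stopifnot(inherits(points, "infinity_points"))
  seed <- as.list(seed)
  if (diff(range(points$x)) > image_w - 1 + 1e-9 ||
      diff(range(points$y)) > image_h - 1 + 1e-9) {
    abort("shape larger than the image; normalize to at most the image size first")
  }
  dx <- seed$x - mean(points$x)
  dy <- seed$y - mean(points$y)
  # pull the shift back so the bounding box stays inside [1, w] x [1, h]
  dx <- clamp_shift(points$x, dx, image_w)
  dy <- clamp_shift(points$y, dy, image_h)
  df <- tibble::tibble(t = points$t,
                       x = as.integer(round_half_away(points$x + dx)),
                       y = as.integer(round_half_away(points$y + dy)))
  df$x <- pmin(pmax(df$x, 1L), as.integer(image_w))
  df$y <- pmin(pmax(df$y, 1L), as.integer(image_h))
  new_infinity_points(df, attr(points, "config"), "placed")
}

clamp_shift <- function(v, d, upper) {
  d <- min(d, upper - max(v))
  max(d, 1 - min(v))
}

#' @exportS3Method ggplot2::autoplot
autoplot.infinity_points <- function(object, ...) {
  frame <- attr(object, "frame")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point(size = 0.8) +
    {if (frame != "unit") ggplot2::scale_y_reverse()} +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("infinity point set (%s frame)", frame))
}
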
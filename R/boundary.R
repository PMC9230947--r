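#' Rasterize a line segment between two pixels
#'
#' Bresenham's line including both endpoints, canonicalized so that
#' reversing the endpoints yields exactly the reversed pixel list.
#' Consecutive pixels are 8-connected.
#'
#' @param p0,p1 Integer pixel endpoints as `c(x, y)` (or one-row data
#'   frames with `x`, `y`).
#' @return Tibble with integer columns `x`, `y`, ordered from `p0` to
#'   `p1`.
#' @export
#' @examples
#' rasterize_segment(c(1, 1), c(4, 1))
rasterize_segment <- function(p0, p1) {
  p0 <- as_xy(p0)
  p1 <- as_xy(p1)
  # canonical direction: lexicographically smaller endpoint first
  if (p1[1] < p0[1] || (p1[1] == p0[1] && p1[2] < p0[2])) {
    out <- rasterize_segment(p1, p0)
    return(out[rev(seq_len(nrow(out))), ])
  }
  x0 <- p0[1]; y0 <- p0[2]; x1 <- p1[1]; y1 <- p1[2]
  dx <- abs(x1 - x0)
  dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  n <- max(dx, -dy) + 1L
  xs <- integer(n)
  ys <- integer(n)
  for (i in seq_len(n)) {
    xs[i] <- x0
    ys[i] <- y0
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  tibble::tibble(x = xs, y = ys)
}

as_xy <- function(p) {
  p <- unlist(as.list(p)[c("x", "y")], use.names = FALSE) %||% as.numeric(p)
  if (length(p) < 2 || anyNA(p[1:2])) abort("expected a pixel as c(x, y)")
  as.integer(p[1:2])
}

#' Extract the intensity profile along one point triple
#'
#' Concatenates the rasterized segments start->mid and mid->end of three
#' consecutive placed curve points (the shared midpoint pixel enters
#' once) and reads the image intensity at every trace pixel.
#'
#' @param image Grayscale matrix.
#' @param triple Three consecutive placed points: a 3-row data frame with
#'   `x`, `y` (e.g. `placed[i:(i+2), ]`).
#' @param source_index Index `i` of the triple (bookkeeping only).
#' @return Tibble of class `intensity_profile` with columns `x`, `y`
#'   (trace pixels) and `value`; attribute `source_index`.
#' @export
extract_profile <- function(image, triple, source_index = NA_integer_) {
  assert_image(image)
  if (nrow(triple) != 3) abort("`triple` must contain exactly three points")
  if (any(triple$x < 1 | triple$x > ncol(image) |
          triple$y < 1 | triple$y > nrow(image))) {
    abort("triple points fall outside the image")
  }
  seg1 <- rasterize_segment(triple[1, ], triple[2, ])
  seg2 <- rasterize_segment(triple[2, ], triple[3, ])
  trace <- dplyr::bind_rows(seg1, seg2[-1, ])
  trace$value <- as.numeric(image[cbind(trace$y, trace$x)])
  structure(trace, source_index = source_index,
            class = c("intensity_profile", class(tibble::tibble())))
}

#' Find peaks with prominence, width and left base in a 1-D profile
#'
#' Local maxima (plateau apexes at the plateau midpoint) are scored by
#' their topographic prominence — the height above the higher of the two
#' bounding valleys, where each valley is the lowest point between the
#' peak and the nearest higher sample (or the signal end) — and by their
#' full width at half prominence (linear interpolation). `left_base` is
#' the rising-side valley index; mapped through a pixel trace it marks
#' the low-to-high intensity boundary the method takes as a landmark.
#'
#' @param values Numeric vector (or an `intensity_profile`, whose
#'   `value` column is used), length >= 3.
#' @return Tibble with columns `apex`, `prominence`, `width`,
#'   `left_base`, `right_base` (possibly zero rows).
#' @export
#' @examples
#' find_profile_peaks(c(0, 5, 0))
find_profile_peaks <- function(values) {
  if (is.data.frame(values)) values <- values$value
  res <- peak_scan(as.numeric(values))
  tibble::tibble(apex = res$apex, prominence = res$prominence,
                 width = res$width, left_base = res$left_base,
                 right_base = res$right_base)
}

# Core peak analysis as plain vectors (hot path: called once per curve
# triple, and exhaustively in the oracle-equivalence checks).
peak_scan <- function(x) {
  n <- length(x)
  none <- list(apex = integer(0), prominence = double(0), width = double(0),
               left_base = integer(0), right_base = integer(0))
  if (n < 3) return(none)
  apexes <- local_maxima(x)
  if (!length(apexes)) return(none)
  prom <- numeric(length(apexes))
  lb <- integer(length(apexes))
  rb <- integer(length(apexes))
  for (k in seq_along(apexes)) {
    p <- apexes[k]
    # walk left until a sample higher than the peak, tracking the minimum
    i <- p - 1L
    left_min <- x[p]
    lb[k] <- p
    while (i >= 1 && x[i] <= x[p]) {
      if (x[i] < left_min) { left_min <- x[i]; lb[k] <- i }
      i <- i - 1L
    }
    i <- p + 1L
    right_min <- x[p]
    rb[k] <- p
    while (i <= n && x[i] <= x[p]) {
      if (x[i] < right_min) { right_min <- x[i]; rb[k] <- i }
      i <- i + 1L
    }
    prom[k] <- x[p] - max(left_min, right_min)
  }
  width <- vapply(seq_along(apexes), function(k) {
    peak_width(x, apexes[k], prom[k], lb[k], rb[k])
  }, double(1))
  keep <- prom > 0
  list(apex = apexes[keep], prominence = prom[keep], width = width[keep],
       left_base = lb[keep], right_base = rb[keep])
}

empty_peaks <- function() {
  tibble::tibble(apex = integer(), prominence = double(), width = double(),
                 left_base = integer(), right_base = integer())
}

# Indices of strict local maxima; a flat plateau bounded by lower samples
# on both sides counts once, at its (floored) midpoint.
local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        out <- c(out, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Full width at half prominence with linear interpolation, evaluated
# between the two bases.
peak_width <- function(x, p, prom, lb, rb) {
  height <- x[p] - prom / 2
  i <- p
  while (i > lb && x[i] > height) i <- i - 1L
  left_ip <- i
  if (x[i] < height) left_ip <- i + (height - x[i]) / (x[i + 1L] - x[i])
  i <- p
  while (i < rb && x[i] > height) i <- i + 1L
  right_ip <- i
  if (x[i] < height) right_ip <- i - (height - x[i]) / (x[i - 1L] - x[i])
  right_ip - left_ip
}

#' Detect flexible landmarks along the placed infinity shape
#'
#' Iterates over every consecutive triple of placed curve points, reads
#' the intensity along the two connecting segments, and keeps each peak
#' whose prominence and half-prominence width both clear their
#' thresholds; the peak's left base — the pixel where intensity turns
#' from low to high — becomes a landmark. Overlapping triples scan each
#' segment twice with different neighbours, which is the redundancy the
#' method relies on. Exact duplicate pixels are dropped (first seen
#' wins); near-duplicates are kept since their descriptor neighbourhoods
#' differ.
#'
#' @param image Grayscale matrix.
#' @param placed Placed `infinity_points` (integer pixels, >= 3 points).
#' @param min_prominence Minimum peak prominence in intensity units;
#'   default 76.5 = 30% of the 8-bit dynamic range. A boundary peak
#'   swings between a dark feature and skin — roughly half the dynamic
#'   range — while specular highlights (nose bridge over forehead) and
#'   skin texture stay well under a third of it, so this keeps
#'   feature-to-skin edges and rejects peaks whose left base would be a
#'   noise-random skin pixel.
#' @param min_width Minimum full width at half prominence, in samples.
#' @param invert Detect dark valleys instead of bright peaks by negating
#'   the profile.
#' @return Tibble of class `facemark_landmarks`: columns `x`, `y`,
#'   `source_index`, `prominence`, `width`.
#' @export
#' @examples
#' face <- generate_upper_face(synthetic_face_spec(rng_seed = 5))
#' ps <- generate_infinity_points() |>
#'   normalize_to_image(ncol(face$image), nrow(face$image)) |>
#'   place_at_seed(find_seed(face$image), ncol(face$image), nrow(face$image))
#' detect_landmarks(face$image, ps)
detect_landmarks <- function(image, placed, min_prominence = 76.5,
                             min_width = 3, invert = FALSE) {
  assert_image(image)
  stopifnot(inherits(placed, "infinity_points"))
  if (!identical(attr(placed, "frame"), "placed")) {
    abort("`placed` must be a placed point set (see place_at_seed())")
  }
  if (nrow(placed) < 3) abort("need at least 3 placed points")
  if (min_prominence < 0 || min_width < 0) abort("thresholds must be >= 0")
  rows <- vector("list", nrow(placed) - 2L)
  for (i in seq_len(nrow(placed) - 2L)) {
    prof <- extract_profile(image, placed[i:(i + 2L), ], source_index = i)
    v <- if (invert) -prof$value else prof$value
    pk <- peak_scan(v)
    sel <- pk$prominence >= min_prominence & pk$width >= min_width
    if (any(sel)) {
      rows[[i]] <- tibble::tibble(
        x = prof$x[pk$left_base[sel]], y = prof$y[pk$left_base[sel]],
        source_index = i, prominence = pk$prominence[sel],
        width = pk$width[sel]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(x = integer(), y = integer(),
                          source_index = integer(), prominence = double(),
                          width = double())
  }
  out <- out[!duplicated(out[, c("x", "y")]), ]
  structure(out, class = c("facemark_landmarks", class(tibble::tibble())))
}

#' @exportS3Method ggplot2::autoplot
autoplot.facemark_landmarks <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(image)) {
    df <- expand.grid(x = seq_len(ncol(image)), y = seq_len(nrow(image)))
    df$value <- as.vector(t(image))
    p <- p + ggplot2::geom_raster(data = df, ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p + ggplot2::geom_point(ggplot2::aes(size = .data$prominence),
                          colour = "red", alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "detected upper-face landmarks", size = "prominence")
}
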
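#' Gradient field of an image blob
#'
#' Central differences `Gx(y,x) = Y(y,x+1) - Y(y,x-1)` and
#' `Gy(y,x) = Y(y+1,x) - Y(y-1,x)` with replicated edges, magnitude
#' `sqrt(Gx^2 + Gy^2)`, and the quadrant-aware arctangent of `Gy/Gx`
#' mapped to degrees in `[0, 360)`. Angles are measured in the image
#' frame (y increasing downward); the convention is internal-consistency
#' only — the descriptor never compares angles across conventions.
#'
#' @param blob Numeric matrix, at least 3 x 3.
#' @return List of class `gradient_field` with matrices `gx`, `gy`,
#'   `magnitude`, `angle`.
#' @export
#' @examples
#' g <- gradient(matrix(rep(1:5, 5), 5, 5, byrow = TRUE))
#' g$gx[3, 3]  # 2 on a unit ramp
gradient <- function(blob) {
  if (!is.matrix(blob) || nrow(blob) < 3 || ncol(blob) < 3) {
    abort("`blob` must be a matrix of at least 3 x 3")
  }
  h <- nrow(blob)
  w <- ncol(blob)
  xr <- pmin(seq_len(w) + 1L, w)
  xl <- pmax(seq_len(w) - 1L, 1L)
  yd <- pmin(seq_len(h) + 1L, h)
  yu <- pmax(seq_len(h) - 1L, 1L)
  gx <- blob[, xr, drop = FALSE] - blob[, xl, drop = FALSE]
  gy <- blob[yd, , drop = FALSE] - blob[yu, , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 360
  ang[mag == 0] <- 0
  structure(list(gx = gx, gy = gy, magnitude = mag, angle = ang),
            class = "gradient_field")
}

#' Extract the square blob around a landmark
#'
#' The blob start is the landmark coordinate minus half the blob size,
#' clamped at the image's near edge; the far side is zero-padded if the
#' blob would overrun the image, so the result is always exactly
#' `size x size`.
#'
#' @param image Grayscale matrix.
#' @param lm Landmark: named list or one-row data frame with `x`, `y`.
#' @param size Even blob side length in pixels (default 20).
#' @return A `size x size` numeric matrix with attribute
#'   `origin = c(x, y)` of its top-left pixel in the image.
#' @export
extract_blob <- function(image, lm, size = 20) {
  assert_image(image)
  if (size %% 2 != 0 || size < 4) abort("`size` must be even and >= 4")
  lm <- as.list(lm)
  half <- size / 2
  x0 <- max(1L, as.integer(lm$x) - as.integer(half))
  y0 <- max(1L, as.integer(lm$y) - as.integer(half))
  xs <- x0:(x0 + size - 1L)
  ys <- y0:(y0 + size - 1L)
  blob <- matrix(0, size, size)
  vx <- xs <= ncol(image)
  vy <- ys <= nrow(image)
  blob[seq_len(sum(vy)), seq_len(sum(vx))] <-
    image[ys[vy], xs[vx], drop = FALSE]
  attr(blob, "origin") <- c(x = x0, y = y0)
  blob
}

#' 72-value HOG descriptor of a 20 x 20 blob
#'
#' The gradient field is pooled into 2 x 2 spatial cells of 10 x 10
#' pixels; each cell accumulates a signed 18-bin orientation histogram
#' (20 degree bins over `[0, 360)`), magnitude-weighted with linear
#' interpolation between the two adjacent bin centres. The four cell
#' histograms are concatenated (cells row-major: top-left, top-right,
#' bottom-left, bottom-right; bins ascending) and L2-normalized as a
#' single block with epsilon 1e-6, giving 4 x 18 = 72 non-negative
#' values.
#'
#' @param blob 20 x 20 numeric matrix (see [extract_blob()]).
#' @return Numeric vector of length 72.
#' @export
hog_descriptor <- function(blob) {
  if (!is.matrix(blob) || !all(dim(blob) == c(20, 20))) {
    abort("`blob` must be exactly 20 x 20")
  }
  g <- gradient(blob)
  desc <- numeric(72)
  cell <- 0L
  for (cy in 0:1) {
    for (cx in 0:1) {
      rows <- (cy * 10 + 1):(cy * 10 + 10)
      cols <- (cx * 10 + 1):(cx * 10 + 10)
      desc[cell * 18 + 1:18] <- orientation_histogram(
        g$angle[rows, cols], g$magnitude[rows, cols], nbins = 18
      )
      cell <- cell + 1L
    }
  }
  desc / sqrt(sum(desc^2) + 1e-6^2)
}

# Magnitude-weighted circular histogram with linear interpolation between
# adjacent bin centres ((k - 0.5) * binwidth).
orientation_histogram <- function(angle, magnitude, nbins) {
  bw <- 360 / nbins
  pos <- angle / bw - 0.5
  k0 <- floor(pos)
  frac <- pos - k0
  b0 <- (as.integer(k0) %% nbins) + 1L
  b1 <- (b0 %% nbins) + 1L
  hist <- numeric(nbins)
  w0 <- as.vector(magnitude * (1 - frac))
  w1 <- as.vector(magnitude * frac)
  for (i in seq_along(w0)) {
    hist[b0[i]] <- hist[b0[i]] + w0[i]
    hist[b1[i]] <- hist[b1[i]] + w1[i]
  }
  hist
}

#' Full feature vector of one landmark
#'
#' @param image Grayscale matrix.
#' @param lm Landmark with `x`, `y`.
#' @param size Blob size (default 20).
#' @param normalize_coords Rescale the two coordinates to `[0, 1]` by the
#'   image dimensions (off by default: raw pixel coordinates).
#' @return Numeric vector of length 74: `(x, y, d1..d72)`.
#' @export
landmark_feature <- function(image, lm, size = 20, normalize_coords = FALSE) {
  lm <- as.list(lm)
  desc <- hog_descriptor(extract_blob(image, lm, size))
  xy <- c(lm$x, lm$y)
  if (normalize_coords) xy <- c(lm$x / ncol(image), lm$y / nrow(image))
  c(xy, desc)
}

#' Feature table for a set of landmarks
#'
#' @param image Grayscale matrix.
#' @param landmarks Tibble from [detect_landmarks()] (needs `x`, `y`;
#'   `prominence`/`width` are carried through if present).
#' @param size,normalize_coords Passed to [landmark_feature()].
#' @return Tibble with `x`, `y`, any carried columns, and `d1`..`d72`.
#' @export
landmark_features <- function(image, landmarks, size = 20,
                              normalize_coords = FALSE) {
  if (!nrow(landmarks)) {
    return(tibble::as_tibble(c(
      list(x = double(), y = double()),
      setNames(rep(list(double()), 72), paste0("d", 1:72))
    )))
  }
  feats <- t(vapply(seq_len(nrow(landmarks)), function(i) {
    landmark_feature(image, landmarks[i, ], size, normalize_coords)
  }, double(74)))
  desc <- tibble::as_tibble(as.data.frame(feats[, 3:74, drop = FALSE]),
                            .name_repair = "minimal")
  names(desc) <- paste0("d", 1:72)
  carried <- intersect(c("source_index", "prominence", "width"), names(landmarks))
  dplyr::bind_cols(
    tibble::tibble(x = feats[, 1], y = feats[, 2]),
    landmarks[, carried, drop = FALSE],
    desc
  )
}
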
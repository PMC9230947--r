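#' Intensity projection profile
#'
#' The vertical projection sums intensities down each column; the
#' horizontal projection sums across each row. On an upper face the nose
#' bridge is the brightest column (vertical maximum) while the eye/brow
#' band is the darkest row region (horizontal minimum), which is what the
#' seed-point rule exploits.
#'
#' @param image Grayscale matrix.
#' @param axis `"vertical"` (per column) or `"horizontal"` (per row).
#' @return Tibble with columns `index` and `value`, attribute `axis`.
#' @export
#' @examples
#' project(matrix(1:4, 2, 2), "vertical")$value  # column sums
project <- function(image, axis = c("vertical", "horizontal")) {
  assert_image(image)
  axis <- match.arg(axis)
  v <- if (axis == "vertical") colSums(image) else rowSums(image)
  structure(tibble::tibble(index = seq_along(v), value = as.numeric(v)),
            axis = axis, class = c("projection_profile", class(tibble::tibble())))
}

# Savitzky-Golay smoothing matrix: projection onto local polynomials of
# degree `polyorder` over a centred window. Row k gives the fitted value
# at offset k - (window+1)/2.
savgol_matrix <- function(window, polyorder) {
  h <- (window - 1) / 2
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  A %*% solve(crossprod(A), t(A))
}

#' Savitzky–Golay smoothing of a projection profile
#'
#' Least-squares local-polynomial smoothing with the defaults used for
#' seed finding: window 31, polynomial order 3. Edges are handled by
#' evaluating the polynomial fitted to the first/last full window, so a
#' profile sampled from a degree <= `polyorder` polynomial is reproduced
#' exactly everywhere. A window longer than the profile is reduced to the
#' largest valid odd window (with a message) rather than failing.
#'
#' @param profile Tibble from [project()] (or any tibble with a `value`
#'   column), or a bare numeric vector.
#' @param window Odd window length.
#' @param polyorder Polynomial degree, `< window`.
#' @return The profile with a `smoothed` column added (or, for vector
#'   input, the smoothed vector).
#' @export
smooth_profile <- function(profile, window = 31, polyorder = 3) {
  vec_in <- is.numeric(profile) && is.null(dim(profile))
  v <- if (vec_in) as.numeric(profile) else profile$value
  n <- length(v)
  if (window %% 2 == 0) abort("`window` must be odd")
  if (window > n) {
    window <- if (n %% 2 == 1) n else n - 1L
    inform(sprintf("smoothing window reduced to %d to fit the profile", window))
  }
  if (polyorder >= window) polyorder <- window - 1L
  Hm <- savgol_matrix(window, polyorder)
  h <- (window - 1) / 2
  sm <- numeric(n)
  mid <- h + 1
  if (n > window) {
    center <- Hm[mid, ]
    for (i in (h + 1):(n - h)) sm[i] <- sum(center * v[(i - h):(i + h)])
    sm[1:h] <- (Hm %*% v[1:window])[1:h]
    sm[(n - h + 1):n] <- (Hm %*% v[(n - window + 1):n])[(mid + 1):window]
  } else {
    sm <- as.numeric(Hm %*% v)
  }
  if (vec_in) return(sm)
  profile$smoothed <- sm
  profile
}

#' Locate the seed point of an upper face
#'
#' The seed anchors the infinity shape: its x is the brightest column of
#' the raw vertical projection (the nose bridge); its y is the darkest
#' row of the *smoothed* horizontal projection. Smoothing merges the
#' three contrast cases (eye darker, brow darker, blended) into one
#' minimum between the brow and eye bands. Ties break to the lowest
#' index.
#'
#' @param image Grayscale upper-face matrix (at least 16 x 32).
#' @param window,polyorder Savitzky–Golay parameters for the horizontal
#'   projection.
#' @param smooth_vertical Also smooth the vertical projection before
#'   taking its maximum (off by default; the nose-bridge maximum is
#'   unambiguous).
#' @return One-row tibble with integer `x`, `y`.
#' @export
#' @examples
#' face <- generate_upper_face(synthetic_face_spec(rng_seed = 3))
#' find_seed(face$image)
find_seed <- function(image, window = 31, polyorder = 3,
                      smooth_vertical = FALSE) {
  assert_image(image)
  if (nrow(image) < 16 || ncol(image) < 32) {
    abort("image below the 16 x 32 minimum for seed finding")
  }
  vert <- project(image, "vertical")
  vv <- if (smooth_vertical) {
    smooth_profile(vert, window, polyorder)$smoothed
  } else {
    vert$value
  }
  horiz <- smooth_profile(project(image, "horizontal"), window, polyorder)
  # zap sub-micro float noise so argmin/argmax ties (flat profiles) resolve
  # to the lowest index deterministically
  tibble::tibble(x = which.max(round(vv, 6))[1],
                 y = which.min(round(horiz$smoothed, 6))[1])
}
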
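#' Traditional 68-landmark index sets
#'
#' The classic 68-point face annotation splits into an upper-face part
#' (jaw corners, both eyebrows, the top of the nose bridge, and the twelve
#' eye-contour points) and a lower-face part (jaw line, lower nose, mouth).
#' When a facial mask covers the lower face only the upper part survives:
#' 26 of the 68 landmarks, about 38% of the total, of which only the 12
#' eye-area points (18% of the total) move appreciably between emotions.
#' These sets motivate replacing the fixed annotation with flexible
#' landmarks and double as analytic test targets.
#'
#' @return A tibble with columns `index` (integer in 1..68) and `set`
#'   (`"upper"` or `"lower"`), one row per landmark index.
#' @export
#' @examples
#' nrow(upper_set())  # 26
#' nrow(lower_set())  # 42
upper_set <- function() {
  idx <- sort(c(1L, 17L, 18:22, 23:27, 28L, 29L, 37:48))
  tibble::tibble(index = as.integer(idx), set = "upper")
}

#' @rdname upper_set
#' @export
lower_set <- function() {
  idx <- sort(c(2:16, 30:36, 49:68))
  tibble::tibble(index = as.integer(idx), set = "lower")
}

# Eye-contour subset of the upper set.
eye_area_set <- function() {
  tibble::tibble(index = 37:48, set = "eye_area")
}

#' Distance between the same landmark under two emotions
#'
#' Euclidean distance in pixels between two placements of one landmark
#' index, e.g. landmark 40 under "neutral" versus "surprise". Upper-face
#' landmarks barely move between emotions (distance near zero) while
#' lower-face landmarks move a lot, which is why a masked face starves
#' fixed-landmark methods of signal.
#'
#' @param a,b One-row data frames (or named lists) with fields `index`,
#'   `x`, `y` and optionally `emotion`. `a$index` must equal `b$index`.
#' @return The distance in pixels (a single non-negative number).
#' @export
#' @examples
#' landmark_distance(list(index = 40, x = 0, y = 0),
#'                   list(index = 40, x = 3, y = 4))  # 5
landmark_distance <- function(a, b) {
  a <- as.list(a)
  b <- as.list(b)
  if (a$index != b$index) {
    abort(sprintf(
      "cannot compare different landmarks (index %s vs %s)",
      a$index, b$index
    ))
  }
  sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
}

#' Counts and shares of the traditional landmark partition
#'
#' @return A tibble with one row per set (`upper`, `lower`, `eye_area`)
#'   giving the landmark `count` and its `percent` of the 68 total,
#'   rounded to the nearest integer (ties away from zero).
#' @export
#' @examples
#' partition_stats()
partition_stats <- function() {
  sets <- list(upper = upper_set(), lower = lower_set(), eye_area = eye_area_set())
  tibble::tibble(
    set = names(sets),
    count = unname(vapply(sets, nrow, integer(1))),
    percent = unname(vapply(sets, function(s) round_half_away(100 * nrow(s) / 68),
                            double(1)))
  )
}

# round() halves-to-even would print 38.2% -> 38 but 17.5 -> 18 is needed;
# use round-half-away-from-zero for all reported integer percentages.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read a 68-landmark sidecar table
#'
#' Reads a CSV with columns `index,x,y,emotion` (one row per landmark per
#' emotion) for running per-landmark displacement analyses on user data.
#'
#' @param path CSV path.
#' @return A tibble with integer `index` and numeric `x`, `y`.
#' @export
read_landmark_table <- function(path) {
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("index", "x", "y", "emotion")
  if (!all(need %in% names(d))) {
    abort(sprintf("landmark table needs columns: %s", paste(need, collapse = ", ")))
  }
  if (any(d$index < 1 | d$index > 68)) abort("landmark indices must lie in 1..68")
  d$index <- as.integer(d$index)
  d
}

#' Per-landmark displacement between two emotions
#'
#' For every landmark index present under both emotions, computes the
#' Euclidean displacement and tags it with its partition set.
#'
#' @param landmarks Tibble as returned by [read_landmark_table()].
#' @param emotion1,emotion2 Emotion labels to compare.
#' @return Tibble with `index`, `set`, `distance`.
#' @export
landmark_displacements <- function(landmarks, emotion1, emotion2) {
  a <- dplyr::filter(landmarks, .data$emotion == emotion1)
  b <- dplyr::filter(landmarks, .data$emotion == emotion2)
  j <- dplyr::inner_join(a, b, by = "index", suffix = c("_1", "_2"))
  part <- dplyr::bind_rows(upper_set(), lower_set())
  j |>
    dplyr::mutate(distance = sqrt((.data$x_2 - .data$x_1)^2 + (.data$y_2 - .data$y_1)^2)) |>
    dplyr::left_join(part, by = "index") |>
    dplyr::select("index", "set", "distance")
}
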
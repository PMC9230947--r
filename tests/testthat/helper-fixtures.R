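# Shared fixture builders (all generated in code; nothing on disk).

default_face <- function(seed = 1, ...) {
  generate_upper_face(synthetic_face_spec(rng_seed = seed, ...))
}

# Seed + normalized/placed curve for an image.
placed_curve <- function(image, config = infinity_config()) {
  s <- find_seed(image)
  generate_infinity_points(config) |>
    normalize_to_image(ncol(image), nrow(image)) |>
    place_at_seed(s, ncol(image), nrow(image))
}

# Minimum distance from each landmark to the true boundary mask.
boundary_distances <- function(landmarks, boundary_mask) {
  bm <- which(boundary_mask, arr.ind = TRUE)
  vapply(seq_len(nrow(landmarks)), function(i) {
    min(sqrt((bm[, 2] - landmarks$x[i])^2 + (bm[, 1] - landmarks$y[i])^2))
  }, double(1))
}

# Small synthetic feature tibble (no image needed) for classifier tests.
fake_features <- function(n, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(runif(n * 72), n, 72) + shift
    colnames(d) <- paste0("d", 1:72)
    dplyr::bind_cols(
      tibble::tibble(x = sample(200, n, TRUE), y = sample(90, n, TRUE),
                     prominence = runif(n, 50, 200)),
      tibble::as_tibble(d)
    )
  })
}

# Separable two-class sequence dataset built from descriptor-shifted rows.
fake_sequence_dataset <- function(n_per_class, max_landmarks = 8, seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    for (cl in c("classA", "classB")) {
      for (i in seq_len(n_per_class)) {
        f <- fake_features(sample(4:max_landmarks, 1),
                           shift = if (cl == "classB") 0.4 else 0,
                           seed = sample.int(1e6, 1))
        out[[length(out) + 1]] <-
          assemble_sequence(f, max_landmarks, label = cl,
                            image_id = sprintf("%s_%d", cl, i))
      }
    }
    out
  })
}
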
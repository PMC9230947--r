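#' Face bounding box
#'
#' @param x,y Top-left pixel of the box (1-based).
#' @param w,h Box width and height in pixels (positive).
#' @return A list of class `face_box`.
#' @export
face_box <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) abort("face box must have positive width and height")
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "face_box")
}

#' Trivial whole-image face detector
#'
#' Face detection is pluggable: any function `image -> face_box` can be
#' used. This default covers the common case of pre-cropped portrait
#' images by returning the full frame; externally supplied boxes come in
#' via [read_face_boxes()].
#'
#' @param image Grayscale matrix.
#' @return A [face_box()] spanning the whole image.
#' @export
detect_face_whole <- function(image) {
  assert_image(image)
  face_box(1, 1, ncol(image), nrow(image))
}

#' Read face boxes from a sidecar CSV
#'
#' @param path CSV with columns `image_id,x,y,w,h`.
#' @return Tibble keyed by `image_id`.
#' @export
read_face_boxes <- function(path) {
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("image_id", "x", "y", "w", "h")
  if (!all(need %in% names(d))) {
    abort(sprintf("face-box table needs columns: %s", paste(need, collapse = ", ")))
  }
  d
}

#' Overlay a synthetic mask on the lower face
#'
#' Paints a flat-coloured trapezoid over the lower `mask_fraction` of the
#' face box, narrowing toward the chin (5% inset per side at the bottom
#' edge), emulating a worn facial mask covering nose, mouth and cheeks.
#' Pixels outside the trapezoid are untouched; applying the mask twice is
#' the same as applying it once.
#'
#' @param image Grayscale matrix.
#' @param box A [face_box()].
#' @param mask_fraction Fraction of the box height covered, in (0, 1).
#' @param mask_color Flat 8-bit intensity of the mask.
#' @return The masked image matrix.
#' @export
overlay_synthetic_mask <- function(image, box, mask_fraction = 0.5,
                                   mask_color = 75) {
  assert_image(image)
  stopifnot(inherits(box, "face_box"))
  if (mask_fraction <= 0 || mask_fraction >= 1) {
    abort("`mask_fraction` must lie strictly between 0 and 1")
  }
  h <- nrow(image)
  w <- ncol(image)
  y_bot <- min(h, box$y + box$h - 1L)
  y_top <- max(1L, box$y + box$h - as.integer(round(mask_fraction * box$h)))
  if (y_top > y_bot) return(image)
  x_l <- max(1L, box$x)
  x_r <- min(w, box$x + box$w - 1L)
  if (is.integer(image)) mask_color <- as.integer(round(mask_color))
  max_inset <- 0.05 * box$w
  for (yy in y_top:y_bot) {
    frac <- if (y_bot == y_top) 1 else (yy - y_top) / (y_bot - y_top)
    inset <- as.integer(round(frac * max_inset))
    xs <- max(x_l, x_l + inset):min(x_r, x_r - inset)
    image[yy, xs] <- mask_color
  }
  image
}

#' Crop the upper-face region
#'
#' Keeps the top `upper_fraction` of the face box: forehead, eyebrows,
#' eyes, and the top of the nose bridge — the part of a masked face that
#' remains visible. The crop origin into the source image is recorded so
#' crop coordinates map back exactly.
#'
#' @param image Grayscale matrix.
#' @param box A [face_box()].
#' @param upper_fraction Fraction of box height kept, in (0, 1). The
#'   default 0.42 reproduces the ~236 x 96 upper crop of a roughly square
#'   portrait face box.
#' @return The cropped matrix with attribute `origin = c(x, y)` (source
#'   coordinates of the crop's top-left pixel).
#' @export
crop_upper_face <- function(image, box, upper_fraction = 0.42) {
  assert_image(image)
  stopifnot(inherits(box, "face_box"))
  if (upper_fraction <= 0 || upper_fraction >= 1) {
    abort("`upper_fraction` must lie strictly between 0 and 1")
  }
  ch <- as.integer(round(upper_fraction * box$h))
  rows <- box$y:(box$y + ch - 1L)
  cols <- box$x:(box$x + box$w - 1L)
  rows <- rows[rows >= 1 & rows <= nrow(image)]
  cols <- cols[cols >= 1 & cols <= ncol(image)]
  if (length(rows) < 16 || length(cols) < 32) {
    abort("upper-face crop below the 16 x 32 minimum size")
  }
  out <- image[rows, cols, drop = FALSE]
  attr(out, "origin") <- c(x = cols[1], y = rows[1])
  out
}
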
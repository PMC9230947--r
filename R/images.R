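#' Image representation
#'
#' Throughout facemark a grayscale image is an integer matrix of 8-bit
#' intensities in `[0, 255]`, indexed `image[y, x]` with `y` the row
#' (top-down) and `x` the column. All pixel coordinates are 1-based.
#'
#' @name facemark-images
NULL

#' Convert an image to an 8-bit grayscale matrix
#'
#' One-channel inputs pass through unchanged; three-channel (RGB) inputs are
#' collapsed with the standard luma weights 0.299 R + 0.587 G + 0.114 B
#' (ITU-R BT.601).
#'
#' @param image An integer matrix (already grayscale), or an `h x w x 3`
#'   array of 8-bit channel values.
#' @return An integer matrix of intensities in `[0, 255]`.
#' @export
#' @examples
#' rgb <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(rgb)  # 76, the red luma
to_grayscale <- function(image) {
  if (is.matrix(image)) {
    return(clip8(image))
  }
  if (is.array(image) && length(dim(image)) == 3) {
    nc <- dim(image)[3]
    if (nc == 1) {
      return(clip8(image[, , 1]))
    }
    if (nc == 3) {
      y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
      return(clip8(y))
    }
    abort(sprintf("unsupported channel count: %d", nc))
  }
  abort("`image` must be a matrix or an h x w x {1,3} array")
}

#' Read an image file as a grayscale intensity matrix
#'
#' @param path PNG file path.
#' @return Integer matrix of 8-bit intensities.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  to_grayscale(if (is.matrix(a)) round(a * 255) else round(a * 255))
}

#' Write a grayscale intensity matrix as a PNG file
#'
#' @param image Integer matrix of 8-bit intensities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(clip8(image) / 255, path)
  invisible(path)
}

# Round and clamp to the 8-bit range, keeping storage mode integer.
clip8 <- function(x) {
  m <- round(x)
  m[m < 0] <- 0
  m[m > 255] <- 255
  storage.mode(m) <- "integer"
  m
}

assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image) || any(dim(image) < 1)) {
    abort(sprintf("`%s` must be a non-empty numeric matrix", arg))
  }
  invisible(image)
}
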
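#' Construct an image plane
#'
#' An image plane is a plain numeric matrix of non-negative intensities with a
#' `bit_depth` attribute (8 or 16). Rows index y (top to bottom), columns
#' index x, so `img[y, x]` is the pixel at column x of row y.
#'
#' @param pixels Numeric matrix of intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Integer, 8 or 16.
#' @return The matrix with class `fc_plane` and a `bit_depth` attribute.
#' @examples
#' img <- image_plane(matrix(0, 32, 32), bit_depth = 8)
#' bit_depth(img)
#' @export
image_plane <- function(pixels, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "fc_invalid_input")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    abort("`bit_depth` must be 8 or 16.", class = "fc_invalid_parameter")
  }
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1)) {
    abort(sprintf("intensities must lie in [0, %d].", 2^bit_depth - 1),
      class = "fc_invalid_input"
    )
  }
  structure(pixels, bit_depth = as.integer(bit_depth), class = c("fc_plane", "matrix", "array"))
}

#' @rdname image_plane
#' @param img An image plane or plain matrix.
#' @export
bit_depth <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) 16L else as.integer(bd)
}

# rewrap a computed pixel matrix with the metadata of a template plane
replane <- function(pixels, template) {
  structure(pixels,
    bit_depth = bit_depth(template),
    class = c("fc_plane", "matrix", "array")
  )
}

#' @export
print.fc_plane <- function(x, ...) {
  cat(sprintf(
    "<image plane> %d x %d px, %d-bit, range [%g, %g]\n",
    nrow(x), ncol(x), bit_depth(x), min(x), max(x)
  ))
  invisible(x)
}

#' Construct a binary mask
#'
#' A binary mask is an integer matrix of 0 (background) and 1 (foreground),
#' the unit of set-arithmetic classification. Foreground is 8-connected and
#' background 4-connected throughout the package.
#'
#' @param pixels A logical or 0/1 numeric matrix.
#' @return An integer 0/1 matrix with class `fc_mask`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix.", class = "fc_invalid_input")
  v <- pixels
  if (is.logical(v)) v <- v * 1L
  if (!all(v %in% c(0, 1))) {
    abort("a binary mask may contain only 0 and 1.", class = "fc_invalid_input")
  }
  structure(matrix(as.integer(v), nrow(pixels), ncol(pixels)),
    class = c("fc_mask", "matrix", "array")
  )
}

as_mask_matrix <- function(mask) {
  if (!is.matrix(mask)) abort("expected a matrix mask.", class = "fc_invalid_input")
  if (is.logical(mask)) mask <- mask * 1L
  mask
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must have identical shapes (%s vs %s).", what,
      paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
    ), class = "fc_invalid_input")
  }
  invisible(TRUE)
}

#' @export
print.fc_mask <- function(x, ...) {
  cat(sprintf(
    "<binary mask> %d x %d px, %d foreground px (%.1f%%)\n",
    nrow(x), ncol(x), sum(x), 100 * mean(x)
  ))
  invisible(x)
}
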
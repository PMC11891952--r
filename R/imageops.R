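#' Rolling-ball background subtraction
#'
#' Estimates a smooth background by grayscale opening with a ball-shaped
#' structuring element of the given radius (the "rolling ball": the envelope
#' traced by a ball rolled beneath the intensity surface) and subtracts it.
#' For radii above 16 px the classic shrink/enlarge speed-up is used: the
#' image is min-reduced by a block factor (4 up to radius 32, 8 beyond), the
#' opening runs on the reduced image with a correspondingly reduced ball, and
#' the background is bilinearly enlarged back and clamped to lie at or below
#' the original image before subtraction. The defaults used by the pipeline
#' are radius 50 for the green channel and 30 for the red channel.
#'
#' @param img Image plane (numeric matrix).
#' @param radius Ball radius in pixels, >= 1.
#' @return Image plane of the same shape and bit depth, clipped to >= 0.
#' @examples
#' img <- image_plane(matrix(40, 64, 64), 8)
#' range(subtract_background(img, 50)) # uniform background fully removed
#' @export
subtract_background <- function(img, radius) {
  if (length(radius) != 1 || !is.finite(radius) || radius < 1) {
    abort("`radius` must be a single value >= 1.", class = "fc_invalid_parameter")
  }
  px <- unclass(img)
  shrink <- if (radius <= 16) 1L else if (radius <= 32) 4L else 8L
  if (shrink == 1L) {
    bg <- gray_open_ball(px, radius)
  } else {
    small <- block_reduce_min(px, shrink)
    bg_small <- gray_open_ball(small, max(1, radius / shrink))
    bg <- bilinear_enlarge(bg_small, shrink, nrow(px), ncol(px))
    bg <- pmin(bg, px) # background may never exceed the data
  }
  replane(pmax(px - bg, 0), img)
}

# grayscale opening with a non-flat ball structuring element, exact
gray_open_ball <- function(px, radius) {
  off <- ball_offsets(radius)
  er <- shift_reduce(px, off, op = "erode")
  shift_reduce(er, off, op = "dilate")
}

ball_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- g$dy^2 + g$dx^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  g$z <- sqrt(pmax(radius^2 - g$dy^2 - g$dx^2, 0))
  g
}

# min/max over translated copies; out-of-bounds pixels are ignored
shift_reduce <- function(px, off, op) {
  h <- nrow(px); w <- ncol(px)
  r <- max(abs(c(off$dy, off$dx)))
  fill <- if (op == "erode") Inf else -Inf
  pad <- matrix(fill, h + 2 * r, w + 2 * r)
  pad[(r + 1):(r + h), (r + 1):(r + w)] <- px
  acc <- matrix(fill, h, w)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]; z <- off$z[i]
    sub <- pad[(r + 1 + dy):(r + h + dy), (r + 1 + dx):(r + w + dx)]
    acc <- if (op == "erode") pmin(acc, sub - z) else pmax(acc, sub + z)
  }
  acc
}

block_reduce_min <- function(px, s) {
  h <- nrow(px); w <- ncol(px)
  hs <- ceiling(h / s); ws <- ceiling(w / s)
  out <- matrix(Inf, hs, ws)
  ri <- rep(seq_len(hs), each = s, length.out = h)
  ci <- rep(seq_len(ws), each = s, length.out = w)
  for (j in seq_len(w)) {
    col_min <- tapply(px[, j], ri, min)
    out[, ci[j]] <- pmin(out[, ci[j]], col_min)
  }
  out
}

bilinear_enlarge <- function(small, s, h, w) {
  # block centres of the reduced grid, in full-resolution coordinates
  ys <- (seq_len(nrow(small)) - 1) * s + (s + 1) / 2
  xs <- (seq_len(ncol(small)) - 1) * s + (s + 1) / 2
  interp1 <- function(grid, at) {
    # indices of the bracketing grid points, clamped at the ends
    lo <- findInterval(at, grid, all.inside = TRUE)
    hi <- lo + 1
    t <- (at - grid[lo]) / (grid[hi] - grid[lo])
    pmin(pmax(t, 0), 1)
  }
  ty <- interp1(ys, seq_len(h)); ly <- findInterval(seq_len(h), ys, all.inside = TRUE)
  tx <- interp1(xs, seq_len(w)); lx <- findInterval(seq_len(w), xs, all.inside = TRUE)
  a <- small[ly, lx, drop = FALSE]
  b <- small[ly + 1, lx, drop = FALSE]
  cc <- small[ly, lx + 1, drop = FALSE]
  d <- small[ly + 1, lx + 1, drop = FALSE]
  wy <- matrix(ty, h, w); wx <- matrix(tx, h, w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + cc * (1 - wy) * wx + d * wy * wx
}

#' Mean smoothing
#'
#' 3x3 uniform mean filter; border pixels average over their in-bounds
#' neighbours only, so constant images pass through unchanged. The pipeline
#' applies this twice in sequence before thresholding.
#'
#' @param img Image plane.
#' @param passes Number of sequential applications (default 1).
#' @return Smoothed image plane (same shape and bit depth).
#' @export
smooth_mean3 <- function(img, passes = 1L) {
  px <- unclass(img) * 1.0
  h <- nrow(px); w <- ncol(px)
  ones <- matrix(1, h, w)
  cnt <- shift_sum(ones)
  for (p in seq_len(passes)) px <- shift_sum(px) / cnt
  replane(px, img)
}

# sum over the 3x3 in-bounds neighbourhood of each pixel
shift_sum <- function(px) {
  h <- nrow(px); w <- ncol(px)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- px
  acc <- matrix(0, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    acc <- acc + pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  }
  acc
}

#' Binary dilation and erosion
#'
#' 3x3 square structuring element, repeated `iterations` times; pixels
#' outside the image are treated as background.
#'
#' @param mask Binary mask.
#' @param iterations Number of repetitions, >= 1.
#' @return Binary mask.
#' @export
mask_dilate <- function(mask, iterations = 1L) {
  morph_iter(mask, iterations, EBImage::dilate)
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, iterations = 1L) {
  morph_iter(mask, iterations, EBImage::erode)
}

morph_iter <- function(mask, iterations, fun) {
  if (iterations < 1) abort("`iterations` must be >= 1.", class = "fc_invalid_parameter")
  m <- as_mask_matrix(mask)
  kern <- EBImage::makeBrush(3, shape = "box")
  x <- EBImage::Image(m)
  for (i in seq_len(iterations)) x <- fun(x, kern)
  binary_mask(EBImage::imageData(x) > 0)
}

#' Fill interior holes
#'
#' Background regions not 4-connected to the image border become foreground;
#' the exterior background is untouched.
#'
#' @param mask Binary mask.
#' @return Binary mask with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- as_mask_matrix(mask)
  bg <- EBImage::bwlabel(EBImage::Image(1L - (m > 0))) # 4-connected background
  lab <- EBImage::imageData(bg)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- lab > 0 & !(lab %in% border_labels)
  binary_mask(m > 0 | hole)
}

#' Watershed separation of fused objects
#'
#' Splits merged binary objects along the valleys of the Euclidean distance
#' transform: regional maxima of the distance map (plateaus within
#' `tolerance` of each other are merged) seed a flooding, and 1-px-wide
#' background dividing lines are inserted between basins so that the split
#' objects are not 8-connected. Objects with a single maximum pass through
#' unchanged. Never creates foreground (`output` is a subset of `mask`).
#'
#' @param mask Binary mask.
#' @param tolerance Minimum distance-map height separating two seeds
#'   (default 0.5).
#' @return Binary mask with dividing lines inserted.
#' @export
watershed_split <- function(mask, tolerance = 0.5) {
  m <- as_mask_matrix(mask)
  if (sum(m) == 0) return(binary_mask(m))
  dm <- EBImage::distmap(EBImage::Image(m > 0))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance, ext = 1))
  lab[m == 0] <- 0L
  # drop pixels 8-adjacent to a basin with a smaller label -> 1-px background
  # lines; removal is one-sided so the smaller-labelled basin keeps its edge
  h <- nrow(lab); w <- ncol(lab)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- lab
  cut <- matrix(FALSE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    cut <- cut | (nb > 0L & nb < lab)
  }
  out <- m
  out[cut] <- 0L
  binary_mask(out)
}

#' Mask set arithmetic
#'
#' `mask_and()` is the pixelwise intersection, `mask_subtract()` the
#' pixelwise set difference (foreground in `a` and not in `b`), and
#' `mask_complement()` the pixelwise inversion. Shapes must match.
#'
#' @param a,b Binary masks of identical shape.
#' @return Binary mask.
#' @export
mask_and <- function(a, b) {
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  check_same_shape(a, b, "masks")
  binary_mask(a > 0 & b > 0)
}

#' @rdname mask_and
#' @export
mask_subtract <- function(a, b) {
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  check_same_shape(a, b, "masks")
  binary_mask(a > 0 & !(b > 0))
}

#' @rdname mask_and
#' @export
mask_complement <- function(a) {
  a <- as_mask_matrix(a)
  binary_mask(!(a > 0))
}
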
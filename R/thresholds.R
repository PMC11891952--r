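#' 256-bin intensity histogram
#'
#' 8-bit planes map intensity to bin directly (bin i = intensity i). Planes
#' of higher depth (or non-integer planes) are linearly scaled from their
#' `[min, max]` range into 256 bins; the bin width and offset are stored so a
#' bin-index threshold can be mapped back to source intensity units with
#' [bin_to_intensity()]. A constant image occupies a single bin.
#'
#' @param img Image plane.
#' @return Object of class `fc_hist256`: integer `counts[256]` plus
#'   `offset`, `bin_width` and `source_bit_depth`.
#' @export
histogram256 <- function(img) {
  px <- as.vector(unclass(img))
  bd <- bit_depth(img)
  if (bd == 8L && all(px == floor(px))) {
    offset <- 0; width <- 1
    bins <- pmin(pmax(px, 0), 255)
  } else {
    lo <- min(px); hi <- max(px)
    if (hi == lo) {
      offset <- lo; width <- 1
      bins <- rep(0, length(px))
    } else {
      width <- (hi - lo) / 256
      offset <- lo
      bins <- pmin(floor((px - lo) / width), 255)
    }
  }
  counts <- tabulate(bins + 1L, nbins = 256L)
  structure(
    list(counts = counts, offset = offset, bin_width = width, source_bit_depth = bd),
    class = "fc_hist256"
  )
}

#' @rdname histogram256
#' @param h A `fc_hist256` histogram.
#' @param t Bin index in 0..255.
#' @return `bin_to_intensity()` returns the source-intensity threshold
#'   equivalent to "foreground = bins above `t`": the midpoint of bin `t`,
#'   so that `apply_threshold(img, bin_to_intensity(h, t))` selects all
#'   pixels falling in bins `t + 1 .. 255`.
#' @export
bin_to_intensity <- function(h, t) {
  h$offset + (t + 0.5) * h$bin_width
}

occupied <- function(h) which(h$counts > 0) - 1L

#' Otsu threshold
#'
#' Returns the bin index maximising the between-class variance of the split
#' into bins `0..t` and `t+1..255`; ties break to the lowest qualifying
#' index. Degenerate single-bin histograms return that bin.
#'
#' @param h A [histogram256()] object.
#' @return Bin index in 0..255.
#' @export
threshold_otsu <- function(h) {
  counts <- as.numeric(h$counts) # doubles: moment sums overflow integer range
  occ <- occupied(h)
  if (length(occ) == 0) abort("empty histogram.", class = "fc_invalid_input")
  if (length(occ) == 1) return(occ[1])
  lev <- 0:255
  n <- sum(counts)
  w0 <- cumsum(counts)                # mass of bins 0..t
  m0 <- cumsum(counts * lev)          # first moment of bins 0..t
  mu <- m0[256] / n
  t <- 0:254
  w0t <- w0[t + 1]; w1t <- n - w0t
  valid <- w0t > 0 & w1t > 0
  mu0 <- m0[t + 1] / w0t
  mu1 <- (m0[256] - m0[t + 1]) / w1t
  bcv <- w0t * w1t * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  t[which.max(bcv)]
}

#' Iterative intermeans ("Default"/IsoData family) threshold
#'
#' Starts at the midpoint of the histogram's occupied range and repeats
#' `t <- round((mean of bins <= t + mean of bins > t) / 2)` until stable.
#' This is the classical iterative intermeans algorithm; no edge-bin
#' special-casing is applied. A single-bin histogram returns that bin.
#'
#' @inheritParams threshold_otsu
#' @return Bin index in 0..255.
#' @export
threshold_default <- function(h) {
  counts <- as.numeric(h$counts)
  occ <- occupied(h)
  if (length(occ) == 0) abort("empty histogram.", class = "fc_invalid_input")
  if (length(occ) == 1) return(occ[1])
  lev <- 0:255
  lo <- min(occ); hi <- max(occ)
  t <- as.integer(round((lo + hi) / 2))
  t <- min(max(t, lo), hi - 1L) # keep both classes non-empty
  for (i in 1:256) {
    below <- counts[1:(t + 1)]; above <- counts[(t + 2):256]
    mlow <- sum(below * lev[1:(t + 1)]) / sum(below)
    mhigh <- sum(above * lev[(t + 2):256]) / sum(above)
    t_new <- as.integer(round((mlow + mhigh) / 2))
    t_new <- min(max(t_new, lo), hi - 1L)
    if (t_new == t) break
    t <- t_new
  }
  t
}

#' Triangle (Zack) threshold
#'
#' Draws the line from the histogram peak to the far end of the longer tail
#' and returns the bin with the maximum perpendicular distance to that line.
#' When the long tail lies to the left of the peak the histogram is mirrored,
#' the computation repeated, and the result un-mirrored. A flat histogram
#' returns the lowest occupied bin.
#'
#' @inheritParams threshold_otsu
#' @return Bin index in 0..255.
#' @export
threshold_triangle <- function(h) {
  counts <- h$counts
  occ <- occupied(h)
  if (length(occ) == 0) abort("empty histogram.", class = "fc_invalid_input")
  if (length(occ) == 1) return(occ[1])
  if (length(unique(counts[occ + 1])) == 1) {
    # flat over its support: no peak to anchor the triangle
    return(min(occ))
  }
  peak <- which.max(counts) - 1L
  lo <- min(occ); hi <- max(occ)
  if ((peak - lo) > (hi - peak)) {
    # long tail on the left: mirror, solve, un-mirror
    t <- triangle_right(rev(counts))
    return(255L - t)
  }
  triangle_right(counts)
}

# triangle threshold assuming the long tail extends to the right of the peak
triangle_right <- function(counts) {
  occ <- which(counts > 0) - 1L
  peak <- which.max(counts) - 1L
  tail_end <- min(255L, max(occ) + 1L) # first (near-)empty bin past the tail
  if (tail_end <= peak) return(peak)
  x1 <- peak; y1 <- counts[peak + 1]
  x2 <- tail_end; y2 <- counts[tail_end + 1]
  xs <- peak:tail_end
  # perpendicular distance from (x, h[x]) to the peak-tail line
  d <- abs((y2 - y1) * xs - (x2 - x1) * counts[xs + 1] + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  xs[which.max(d)]
}

#' Threshold an image plane into a binary mask
#'
#' Pixels with intensity strictly greater than `t` become foreground; both
#' dyes in this assay are bright on a dark background.
#'
#' @param img Image plane.
#' @param t Intensity threshold (source units).
#' @return Binary mask of the same shape.
#' @export
apply_threshold <- function(img, t) {
  binary_mask(unclass(img) > t)
}
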
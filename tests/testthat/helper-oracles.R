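# Brute-force reference implementations used as independent oracles.
# All are direct, loop-based transcriptions of the definitions; none share
# code with the package internals they check.

# grayscale opening by a ball structuring element, looped over every pixel
oracle_opening_ball <- function(px, radius) {
  r <- floor(radius)
  offs <- list()
  for (dy in -r:r) for (dx in -r:r) {
    if (dy^2 + dx^2 <= radius^2) {
      offs[[length(offs) + 1]] <- c(dy, dx, sqrt(radius^2 - dy^2 - dx^2))
    }
  }
  h <- nrow(px); w <- ncol(px)
  er <- matrix(NA_real_, h, w)
  for (y in 1:h) for (x in 1:w) {
    m <- Inf
    for (o in offs) {
      yy <- y + o[1]; xx <- x + o[2]
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w) m <- min(m, px[yy, xx] - o[3])
    }
    er[y, x] <- m
  }
  op <- matrix(NA_real_, h, w)
  for (y in 1:h) for (x in 1:w) {
    m <- -Inf
    for (o in offs) {
      yy <- y + o[1]; xx <- x + o[2]
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w) m <- max(m, er[yy, xx] + o[3])
    }
    op[y, x] <- m
  }
  op
}

# 3x3 in-bounds neighbourhood mean, looped
oracle_mean3 <- function(px) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(NA_real_, h, w)
  for (y in 1:h) for (x in 1:w) {
    vals <- c()
    for (dy in -1:1) for (dx in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w) vals <- c(vals, px[yy, xx])
    }
    out[y, x] <- mean(vals)
  }
  out
}

# hole filling by flood-filling 4-connected background from the border
oracle_fill_holes <- function(m) {
  h <- nrow(m); w <- ncol(m)
  outside <- matrix(FALSE, h, w)
  queue <- list()
  push <- function(y, x) {
    if (y >= 1 && y <= h && x >= 1 && x <= w && !outside[y, x] && m[y, x] == 0) {
      outside[y, x] <<- TRUE
      queue[[length(queue) + 1]] <<- c(y, x)
    }
  }
  for (y in 1:h) { push(y, 1); push(y, w) }
  for (x in 1:w) { push(1, x); push(h, x) }
  while (length(queue) > 0) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    push(p[1] - 1, p[2]); push(p[1] + 1, p[2])
    push(p[1], p[2] - 1); push(p[1], p[2] + 1)
  }
  (m > 0 | !outside) * 1L
}

# 8-connected component membership by repeated flood fill, raster order
oracle_components <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  next_label <- 0L
  for (y in 1:h) for (x in 1:w) {
    if (m[y, x] > 0 && lab[y, x] == 0L) {
      next_label <- next_label + 1L
      stack <- list(c(y, x))
      lab[y, x] <- next_label
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dy in -1:1) for (dx in -1:1) {
          yy <- p[1] + dy; xx <- p[2] + dx
          if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
              m[yy, xx] > 0 && lab[yy, xx] == 0L) {
            lab[yy, xx] <- next_label
            stack[[length(stack) + 1]] <- c(yy, xx)
          }
        }
      }
    }
  }
  lab
}

# exhaustive between-class-variance maximiser, lowest-index tie-break
oracle_otsu <- function(counts) {
  n <- sum(counts)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1)]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:(t + 1)] * (0:t)) / w0
    mu1 <- sum(counts[(t + 2):256] * ((t + 1):255)) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-9) { best_v <- v; best_t <- t }
  }
  best_t
}

# direct intermeans iteration from the midpoint
oracle_isodata <- function(counts) {
  occ <- which(counts > 0) - 1L
  lo <- min(occ); hi <- max(occ)
  t <- min(max(127L, lo), hi - 1L)
  repeat {
    below <- 0:t; above <- (t + 1):255
    ml <- sum(counts[below + 1] * below) / sum(counts[below + 1])
    mh <- sum(counts[above + 1] * above) / sum(counts[above + 1])
    t2 <- as.integer(round((ml + mh) / 2))
    t2 <- min(max(t2, lo), hi - 1L)
    if (t2 == t) return(t)
    t <- t2
  }
}

# exhaustive max-perpendicular-distance scan for the triangle method
oracle_triangle <- function(counts) {
  occ <- which(counts > 0) - 1L
  peak <- which.max(counts) - 1L
  lo <- min(occ); hi <- max(occ)
  mirrored <- (peak - lo) > (hi - peak)
  cc <- if (mirrored) rev(counts) else counts
  occ2 <- which(cc > 0) - 1L
  p <- which.max(cc) - 1L
  e <- min(255L, max(occ2) + 1L)
  x1 <- p; y1 <- cc[p + 1]; x2 <- e; y2 <- cc[e + 1]
  best_d <- -Inf; best_b <- p
  for (bx in p:e) {
    d <- abs((y2 - y1) * bx - (x2 - x1) * cc[bx + 1] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
    if (d > best_d + 1e-12) { best_d <- d; best_b <- bx }
  }
  if (mirrored) 255L - best_b else best_b
}

# explicit two-way ANOVA decomposition over the subjects x raters layout
oracle_anova_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssr <- 0; ssc <- 0; sse <- 0
  rm <- sapply(1:n, function(i) sum(x[i, ]) / k)
  cm <- sapply(1:k, function(j) sum(x[, j]) / n)
  for (i in 1:n) ssr <- ssr + k * (rm[i] - gm)^2
  for (j in 1:k) ssc <- ssc + n * (cm[j] - gm)^2
  for (i in 1:n) for (j in 1:k) sse <- sse + (x[i, j] - rm[i] - cm[j] + gm)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

# geometry helpers for fixtures
make_disk_mask <- function(h, w, cy, cx, r) {
  d2 <- outer((1:h - cy)^2, (1:w - cx)^2, "+")
  binary_mask(d2 <= r^2)
}

random_blob_mask <- function(h, w, n_seeds = 3, grow = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  for (i in seq_len(n_seeds)) {
    m[sample(2:(h - 1), 1), sample(2:(w - 1), 1)] <- 1L
  }
  unclass(mask_dilate(binary_mask(m), grow))
}

# pipeline configuration matched to the synthetic generator's optics: the
# scenes are rendered essentially unblurred, so a compact PSF is the
# physically appropriate deconvolution kernel
scene_config <- function(mode = "TR", ...) {
  pipeline_config(mode,
    optics_green = optics_params(488, 0.3, pixel_spacing = 300, psf_size = 31),
    optics_red = optics_params(561, 0.3, pixel_spacing = 300, psf_size = 31),
    ...
  )
}
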
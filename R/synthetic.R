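#' Specification of a synthetic scene
#'
#' Describes a simulated field of view emulating the staining logic of the
#' assay: viable cells fluoresce green only (6-CF), apoptotic cells green
#' and red co-localised (6-CF + AnnCy3), necrotic cells red only with the
#' signal accumulated in punctate foci inside the cell and no green. Cells
#' are flat-top disks with 2-px Gaussian edge feathering on a dim background
#' with optional low-frequency shading and Gaussian noise, rendered at
#' 16 bits.
#'
#' Default levels emulate healthy spinning-disk data: background ~800,
#' signal ~12000 (signal-to-noise (signal - background)/noise_sd ~ 75 at
#' the default noise), cell radii 10-16 px as seen with a 10x objective.
#' `min_separation` is the minimum gap between cell footprints; negative
#' values force the requested overlap (touching cells).
#'
#' @param shape `(height, width)` in px.
#' @param n_viable,n_apoptotic,n_necrotic Cell counts per class.
#' @param radius_range Cell radius interval in px.
#' @param min_separation Minimum footprint gap in px (may be negative).
#' @param background_level,signal_level Intensities (16-bit units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param shading_amplitude Low-frequency shading as a fraction of
#'   `background_level`.
#' @param necrotic_foci Punctate foci per necrotic cell.
#' @param n_touching_pairs Pairs of viable cells rendered fused (centre
#'   distance `r1 + r2 - 4` px) so that a watershed neck exists between
#'   them; each pair contributes two viable cells to the ground truth.
#' @param seed Integer seed; scenes are bit-reproducible from it.
#' @return A list of class `fc_scene_spec`.
#' @export
scene_spec <- function(shape = c(512, 512), n_viable = 5, n_apoptotic = 2,
                       n_necrotic = 3, radius_range = c(10, 16),
                       min_separation = 6, background_level = 800,
                       signal_level = 12000, noise_sd = 150,
                       shading_amplitude = 0.1, necrotic_foci = 6,
                       n_touching_pairs = 0, seed = 1L) {
  if (any(c(n_viable, n_apoptotic, n_necrotic) < 0)) {
    abort("cell counts must be >= 0.", class = "fc_invalid_parameter")
  }
  if (signal_level <= background_level) {
    abort("`signal_level` must exceed `background_level`.", class = "fc_invalid_parameter")
  }
  if (max(radius_range) * 2 >= min(shape)) {
    abort("`radius_range` does not fit the canvas.", class = "fc_invalid_parameter")
  }
  structure(
    list(
      shape = as.integer(shape), n_viable = n_viable, n_apoptotic = n_apoptotic,
      n_necrotic = n_necrotic, radius_range = radius_range,
      min_separation = min_separation, background_level = background_level,
      signal_level = signal_level, noise_sd = noise_sd,
      shading_amplitude = shading_amplitude, necrotic_foci = necrotic_foci,
      n_touching_pairs = n_touching_pairs, seed = as.integer(seed)
    ),
    class = "fc_scene_spec"
  )
}

# per-cell RNG substream: adding a cell never reshuffles earlier cells
cell_seed <- function(seed, i) (as.integer(seed) * 10007L + i * 131L) %% 2147483562L

#' Generate a synthetic three-channel scene with ground truth
#'
#' Places the requested cells by rejection sampling (cells keep at least
#' `min_separation` px between footprints; placement failure after bounded
#' retries raises a capacity error reporting the counts placed so far) and
#' renders the green, red and transmitted-light planes at 16 bits. Each cell
#' draws its geometry from its own seeded RNG substream, so scenes are
#' bit-reproducible and stable under count changes.
#'
#' @param spec A [scene_spec()].
#' @return A list with `stack` (a [channel_stack()]) and `truth` (class
#'   `fc_truth`: a tibble of per-cell centre, radius and class, plus a
#'   `counts` attribute with per-class totals).
#' @examples
#' sc <- generate_scene(scene_spec(shape = c(128, 128), n_viable = 2,
#'   n_apoptotic = 1, n_necrotic = 1, seed = 7))
#' attr(sc$truth, "counts")
#' @export
generate_scene <- function(spec = scene_spec()) {
  h <- spec$shape[1]; w <- spec$shape[2]
  classes <- rep(c("viable", "apoptotic", "necrotic"),
    times = c(spec$n_viable, spec$n_apoptotic, spec$n_necrotic)
  )
  # placement units: one per isolated cell plus one per fused viable pair
  units <- c(as.list(classes), rep(list("viable_pair"), spec$n_touching_pairs))
  margin_pad <- 8 # keep cells clear of borders so edge exclusion is inert
  cells <- list()
  for (i in seq_along(units)) {
    rng <- cell_rng(cell_seed(spec$seed, i))
    is_pair <- identical(units[[i]], "viable_pair")
    ok <- FALSE
    for (try in 1:500) {
      if (is_pair) {
        r1 <- rng$unif(1, spec$radius_range[1], spec$radius_range[2])
        r2 <- rng$unif(1, spec$radius_range[1], spec$radius_range[2])
        ang <- rng$unif(1, 0, 2 * pi)
        ext <- r1 + r2 # generous bound on the dumbbell half-extent
        cy0 <- rng$unif(1, ext + margin_pad, h - ext - margin_pad)
        cx0 <- rng$unif(1, ext + margin_pad, w - ext - margin_pad)
        d <- r1 + r2 - 4 # fused with a watershed-separable neck
        cand <- list(
          list(cy = cy0 - d / 2 * sin(ang), cx = cx0 - d / 2 * cos(ang), r = r1),
          list(cy = cy0 + d / 2 * sin(ang), cx = cx0 + d / 2 * cos(ang), r = r2)
        )
      } else {
        r <- rng$unif(1, spec$radius_range[1], spec$radius_range[2])
        cand <- list(list(
          cy = rng$unif(1, r + margin_pad, h - r - margin_pad),
          cx = rng$unif(1, r + margin_pad, w - r - margin_pad), r = r
        ))
      }
      clash <- FALSE
      for (cc in cand) {
        for (p in cells) {
          # members of one pair are meant to overlap; everyone else keeps
          # the separation gap
          if (!is.null(p$unit) && p$unit == i) next
          if (sqrt((cc$cy - p$cy)^2 + (cc$cx - p$cx)^2) <
              cc$r + p$r + spec$min_separation) {
            clash <- TRUE; break
          }
        }
        if (clash) break
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) {
      abort(sprintf(
        "could not place unit %d of %d (placed %d cells) at min_separation %.1f.",
        i, length(units), length(cells), spec$min_separation
      ), class = "fc_capacity_error")
    }
    for (cc in cand) {
      cls <- if (is_pair) "viable" else units[[i]]
      cells[[length(cells) + 1]] <- list(
        cy = cc$cy, cx = cc$cx, r = cc$r, class = cls, unit = i, rng = rng
      )
    }
  }
  green <- matrix(0, h, w)
  red <- matrix(0, h, w)
  footprint <- matrix(0, h, w)
  for (cell in cells) {
    disk <- render_disk(h, w, cell$cy, cell$cx, cell$r)
    footprint <- pmax(footprint, disk$profile)
    if (cell$class %in% c("viable", "apoptotic")) {
      green <- add_patch(green, disk)
    }
    if (cell$class == "apoptotic") {
      red <- add_patch(red, disk)
    }
    if (cell$class == "necrotic") {
      red <- add_patch(red, render_foci(cell, h, w, spec$necrotic_foci))
    }
  }
  # background: level + low-frequency shading + Gaussian noise
  set.seed(cell_seed(spec$seed, 0L))
  ys <- seq_len(h); xs <- seq_len(w)
  shading <- spec$shading_amplitude * spec$background_level *
    outer(sin(pi * ys / h), sin(pi * xs / w))
  bg <- spec$background_level + shading
  noise <- function() {
    if (spec$noise_sd > 0) matrix(rnorm(h * w, 0, spec$noise_sd), h, w) else 0
  }
  amp <- spec$signal_level - spec$background_level
  clip16 <- function(m) matrix(pmin(pmax(round(m), 0), 65535), h, w)
  green_px <- clip16(bg + amp * green + noise())
  red_px <- clip16(bg + amp * red + noise())
  trans_px <- clip16(50000 - 20000 * (footprint > 0.5) + noise())
  truth <- purrr::map_dfr(cells, function(cell) {
    tibble(cy = cell$cy, cx = cell$cx, radius = cell$r, class = cell$class)
  })
  counts <- list(
    viable = sum(truth$class == "viable"),
    apoptotic = sum(truth$class == "apoptotic"),
    necrotic = sum(truth$class == "necrotic")
  )
  counts$total <- counts$viable + counts$apoptotic + counts$necrotic
  attr(truth, "counts") <- counts
  class(truth) <- c("fc_truth", class(truth))
  stack <- channel_stack(
    image_plane(green_px, 16L), image_plane(red_px, 16L), image_plane(trans_px, 16L)
  )
  list(stack = stack, truth = truth)
}

# tiny deterministic LCG: each cell owns an isolated stream that never
# touches R's global RNG state
cell_rng <- function(seed) {
  env <- new.env()
  env$state <- as.numeric(seed) %% 2^32
  draw <- function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      env$state <- (1664525 * env$state + 1013904223) %% 2^32
      out[i] <- env$state / 2^32
    }
    out
  }
  list(
    unif = function(n, lo, hi) lo + (hi - lo) * draw(n)
  )
}

# flat-top disk with 2-px Gaussian edge feathering, rendered locally
render_disk <- function(h, w, cy, cx, r) {
  pad <- ceiling(r + 4)
  y0 <- max(1, floor(cy - pad)); y1 <- min(h, ceiling(cy + pad))
  x0 <- max(1, floor(cx - pad)); x1 <- min(w, ceiling(cx + pad))
  ys <- y0:y1; xs <- x0:x1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  core <- r - 2
  prof <- ifelse(d <= core, 1, exp(-(d - core)^2 / (2 * 1^2)))
  prof[d > r + 3] <- 0
  list(ys = ys, xs = xs, profile_local = prof,
       profile = local_to_full(prof, ys, xs, h, w))
}

local_to_full <- function(prof, ys, xs, h, w) {
  full <- matrix(0, h, w)
  full[ys, xs] <- prof
  full
}

add_patch <- function(plane, patch) {
  if (is.list(patch)) patch <- patch$profile
  pmax(plane, patch)
}

# punctate red foci inside a necrotic cell: overlapping Gaussian spots whose
# union forms one blob within the cell footprint
render_foci <- function(cell, h, w, n_foci) {
  r <- cell$r
  sigma <- r / 3
  offs_r <- cell$rng$unif(n_foci, 0, 0.45 * r)
  offs_a <- cell$rng$unif(n_foci, 0, 2 * pi)
  fy <- cell$cy + offs_r * sin(offs_a)
  fx <- cell$cx + offs_r * cos(offs_a)
  pad <- ceiling(r + 4)
  y0 <- max(1, floor(cell$cy - pad)); y1 <- min(h, ceiling(cell$cy + pad))
  x0 <- max(1, floor(cell$cx - pad)); x1 <- min(w, ceiling(cell$cx + pad))
  ys <- y0:y1; xs <- x0:x1
  acc <- matrix(0, length(ys), length(xs))
  for (i in seq_len(n_foci)) {
    d2 <- outer((ys - fy[i])^2, (xs - fx[i])^2, "+")
    acc <- acc + exp(-d2 / (2 * sigma^2))
  }
  acc <- acc / max(acc)
  local_to_full(acc, ys, xs, h, w)
}

#' Score predicted counts against ground truth
#'
#' @param counts A `counts` list (viable/apoptotic/necrotic/total), e.g.
#'   `classify(...)$counts`.
#' @param truth The `truth` component of [generate_scene()].
#' @return Tibble with one row per class (and the total): true and predicted
#'   counts, absolute and relative errors (relative error is 0 when both are
#'   zero).
#' @export
score_against_truth <- function(counts, truth) {
  tc <- attr(truth, "counts")
  cls <- c("viable", "apoptotic", "necrotic", "total")
  purrr::map_dfr(cls, function(k) {
    tru <- tc[[k]]; pred <- counts[[k]]
    abs_err <- abs(pred - tru)
    rel <- if (tru == 0) (if (abs_err > 0) Inf else 0) else abs_err / tru
    tibble(
      class = k, true = tru, predicted = pred,
      abs_error = abs_err, rel_error = rel
    )
  })
}
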
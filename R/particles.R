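#' Label 8-connected components
#'
#' Foreground components are 8-connected (background 4-connected, the
#' convention used throughout). Labels 1..K are assigned in raster order
#' (row by row, left to right) of each component's first pixel.
#'
#' @param mask Binary mask.
#' @return Integer matrix of labels, 0 = background; attribute
#'   `n_components` carries K.
#' @export
label_components <- function(mask) {
  m <- as_mask_matrix(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m > 0))) # 4-connected base pass
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  k <- max(lab)
  if (k > 0) {
    # union-find merge of diagonal adjacencies -> 8-connectivity
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
    h <- nrow(lab); w <- ncol(lab)
    if (h > 1 && w > 1) {
      a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
      a2 <- lab[-1, -w]; b2 <- lab[-h, -1]   # up-right diagonal
      pairs <- rbind(
        cbind(as.vector(a1), as.vector(b1)),
        cbind(as.vector(a2), as.vector(b2))
      )
      pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
      pairs <- unique(pairs)
      for (i in seq_len(nrow(pairs))) union(pairs[i, 1], pairs[i, 2])
    }
    root <- vapply(seq_len(k), find, integer(1))
    lab[lab > 0] <- root[lab[lab > 0]]
    # relabel 1..K in raster order of first pixel (row-major)
    h <- nrow(lab)
    raster_index <- function(flat_idx) { # column-major flat index -> raster rank
      r <- (flat_idx - 1) %% h + 1
      cc <- (flat_idx - 1) %/% h + 1
      (r - 1) * ncol(lab) + cc
    }
    fg <- which(lab > 0)
    first_raster <- tapply(raster_index(fg), lab[fg], min)
    ord <- names(sort(first_raster))
    remap <- integer(max(lab))
    remap[as.integer(ord)] <- seq_along(ord)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  structure(lab, n_components = max(lab), class = c("fc_labels", "matrix", "array"))
}

#' Measure one particle
#'
#' Area is the pixel count; perimeter is the length of the particle's outer
#' boundary, measured as the convex outline traced through the pixel-corner
#' points (the package's fixed convention — exact for rectangles, and within
#' a few percent of the true circumference for rasterised disks; it
#' overestimates circularity for strongly concave shapes). Circularity is
#' `min(1, 4 * pi * area / perimeter^2)`. With `include_holes` the component
#' is hole-filled before measurement (the stored mask is untouched).
#' Intensity statistics are taken from `reference` over the component's
#' (filled) pixels.
#'
#' @param labels A [label_components()] labelling.
#' @param label Label to measure.
#' @param reference Image plane for intensity statistics (optional).
#' @param include_holes Fill interior holes before measuring (default TRUE).
#' @return One-row tibble: label, area, perimeter, circularity, centroid_x,
#'   centroid_y, touches_edge, mean_intensity, integrated_density.
#' @export
measure_particle <- function(labels, label, reference = NULL, include_holes = TRUE) {
  lab <- unclass(labels)
  idx <- which(lab == label, arr.ind = TRUE)
  if (nrow(idx) == 0) abort(sprintf("label %s not found.", label), class = "fc_not_found")
  h <- nrow(lab); w <- ncol(lab)
  # work on the component's padded bounding box: hole filling and boundary
  # tracing cost then scale with the particle, not the image
  y0 <- max(1, min(idx[, 1]) - 1); y1 <- min(h, max(idx[, 1]) + 1)
  x0 <- max(1, min(idx[, 2]) - 1); x1 <- min(w, max(idx[, 2]) + 1)
  sel <- lab[y0:y1, x0:x1, drop = FALSE] == label
  if (include_holes) sel <- unclass(fill_holes(binary_mask(sel * 1L))) > 0
  sub_idx <- which(sel, arr.ind = TRUE)
  ys <- sub_idx[, 1] + y0 - 1; xs <- sub_idx[, 2] + x0 - 1
  area <- length(ys)
  per <- corner_hull_perimeter(xs, ys)
  circ <- min(1, 4 * pi * area / per^2)
  edge <- any(ys == 1 | ys == h | xs == 1 | xs == w)
  if (!is.null(reference)) {
    vals <- unclass(reference)[cbind(ys, xs)]
    mi <- mean(vals); intden <- sum(vals)
  } else {
    mi <- NA_real_; intden <- NA_real_
  }
  tibble(
    label = as.integer(label), area = area, perimeter = per,
    circularity = circ, centroid_x = mean(xs), centroid_y = mean(ys),
    touches_edge = edge, mean_intensity = mi, integrated_density = intden
  )
}

# perimeter of the convex outline through the pixel-corner points
corner_hull_perimeter <- function(xs, ys) {
  cx <- c(xs - 0.5, xs - 0.5, xs + 0.5, xs + 0.5)
  cy <- c(ys - 0.5, ys + 0.5, ys - 0.5, ys + 0.5)
  pts <- unique(cbind(cx, cy))
  if (nrow(pts) < 3) return(4) # single pixel corners collapse defensively
  hull <- chull(pts[, 1], pts[, 2])
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
}

#' Particle acceptance gate
#'
#' The size (px^2) and circularity intervals a particle must fall in to be
#' counted. The validated gate sets per image class and mode are in
#' [pipeline_config()].
#'
#' @param size_min,size_max Area interval in px^2 (`size_max` may be `Inf`).
#' @param circ_min,circ_max Circularity interval within `[0, 1]`.
#' @return A list of class `fc_gate`.
#' @examples
#' gate_params(100, Inf, 0.2, 1) # "0.2-1; 100-infinity"
#' @export
gate_params <- function(size_min = 0, size_max = Inf, circ_min = 0, circ_max = 1) {
  if (!(circ_min >= 0 && circ_min <= circ_max && circ_max <= 1)) {
    abort("need 0 <= circ_min <= circ_max <= 1.", class = "fc_invalid_parameter")
  }
  if (!(size_min >= 0 && size_min <= size_max)) {
    abort("need 0 <= size_min <= size_max.", class = "fc_invalid_parameter")
  }
  structure(
    list(size_min = size_min, size_max = size_max,
         circ_min = circ_min, circ_max = circ_max),
    class = "fc_gate"
  )
}

#' Gated particle analysis
#'
#' Labels the mask, measures every component, rejects those failing the size
#' gate, the circularity gate or (with `exclude_edges`) touching any image
#' border, and numbers the accepted particles consecutively in raster order.
#' The overlay codes accepted particles by their number and rejected ones as
#' -1 (rendered white, unnumbered, by [autoplot.fc_particles()]).
#'
#' @param mask Binary mask to analyse.
#' @param gate A [gate_params()] acceptance gate.
#' @param exclude_edges Reject particles touching an image border.
#' @param include_holes Fill holes before measurement.
#' @param reference Image plane for intensity statistics (same shape).
#' @return Object of class `fc_particles`: list with `records` (tibble of
#'   all particles, accepted flag and number), `summary` (one-row tibble of
#'   accepted-particle statistics: count, total_area, average_size,
#'   percent_area, mean, integrated_density) and `overlay` (integer matrix).
#' @export
analyze_particles <- function(mask, gate = gate_params(), exclude_edges = TRUE,
                              include_holes = TRUE, reference = NULL) {
  m <- as_mask_matrix(mask)
  if (!is.null(reference)) check_same_shape(m, unclass(reference), "mask and reference")
  labels <- label_components(m)
  k <- attr(labels, "n_components")
  records <- purrr::map_dfr(seq_len(k), function(i) {
    measure_particle(labels, i, reference = reference, include_holes = include_holes)
  })
  if (k == 0) {
    records <- measure_particle(label_components(matrix(1L, 1, 1)), 1)[0, ]
  }
  accepted <- if (k > 0) {
    records$area >= gate$size_min & records$area <= gate$size_max &
      records$circularity >= gate$circ_min & records$circularity <= gate$circ_max &
      (!exclude_edges | !records$touches_edge)
  } else logical(0)
  records$accepted <- accepted
  records$number <- NA_integer_
  records$number[accepted] <- seq_len(sum(accepted)) # raster order: labels are raster-ordered
  overlay <- matrix(0L, nrow(m), ncol(m))
  lab <- unclass(labels)
  if (k > 0) {
    code <- integer(k)
    code[!accepted] <- -1L
    code[accepted] <- records$number[accepted]
    overlay[lab > 0] <- code[lab[lab > 0]]
  }
  acc <- records[accepted, , drop = FALSE]
  total_area <- sum(acc$area)
  summary <- tibble(
    count = nrow(acc),
    total_area = total_area,
    average_size = if (nrow(acc) > 0) total_area / nrow(acc) else 0,
    percent_area = 100 * total_area / (nrow(m) * ncol(m)),
    mean = if (nrow(acc) > 0) mean(acc$mean_intensity) else NA_real_,
    integrated_density = if (nrow(acc) > 0) mean(acc$integrated_density) else NA_real_
  )
  structure(
    list(records = records, summary = summary, overlay = overlay, gate = gate),
    class = "fc_particles"
  )
}

#' @export
print.fc_particles <- function(x, ...) {
  cat(sprintf(
    "<particle analysis> %d particles measured, %d accepted\n",
    nrow(x$records), x$summary$count
  ))
  print(x$summary)
  invisible(x)
}
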
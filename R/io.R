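#' Three-channel stack of one field of view
#'
#' The registered green (6-CF), red (AnnCy3) and transmitted-light planes of
#' one image. The transmitted plane is carried through to outputs but plays
#' no part in the computation.
#'
#' @param green,red,transmitted Image planes of identical shape.
#' @param source_path Optional originating file path.
#' @param pixel_spacing Optional nm/px calibration metadata.
#' @return A list of class `fc_stack`.
#' @export
channel_stack <- function(green, red, transmitted, source_path = NA_character_,
                          pixel_spacing = NA_real_) {
  check_same_shape(green, red, "green and red planes")
  check_same_shape(green, transmitted, "green and transmitted planes")
  structure(
    list(
      green = green, red = red, transmitted = transmitted,
      source_path = source_path, pixel_spacing = pixel_spacing
    ),
    class = "fc_stack"
  )
}

#' @export
print.fc_stack <- function(x, ...) {
  cat(sprintf(
    "<channel stack> %d x %d px, %d-bit (green, red, transmitted)\n",
    nrow(x$green), ncol(x$green), bit_depth(x$green)
  ))
  invisible(x)
}

#' Read a multi-page TIFF stack
#'
#' Pages 1/2/3 map to green/red/transmitted by convention (override with
#' `channel_order`). Grayscale 8- or 16-bit pages are accepted; RGB pages
#' and stacks with fewer than three pages or mixed shapes are rejected.
#'
#' @param path TIFF file with at least three grayscale pages.
#' @param channel_order Page order, a permutation of
#'   `c("green", "red", "transmitted")`.
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, channel_order = c("green", "red", "transmitted")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "fc_io_error")
  stopifnot(setequal(channel_order, c("green", "red", "transmitted")))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 3) {
    abort(sprintf(
      "stack must contain green, red and transmitted pages (got %d page%s).",
      length(pages), if (length(pages) == 1) "" else "s"
    ), class = "fc_format_error")
  }
  pages <- pages[1:3]
  for (p in pages) {
    if (length(dim(p)) > 2) {
      abort("RGB pages are not supported; supply grayscale channels.",
        class = "fc_format_error"
      )
    }
  }
  if (!all(vapply(pages, function(p) identical(dim(p), dim(pages[[1]])), logical(1)))) {
    abort("stack pages have mixed shapes.", class = "fc_format_error")
  }
  bd <- if (max(vapply(pages, max, numeric(1))) > 255) 16L else 8L
  planes <- lapply(pages, function(p) image_plane(p, bd))
  names(planes) <- channel_order
  channel_stack(planes$green, planes$red, planes$transmitted, source_path = path)
}

#' Write a stack (e.g. a synthetic scene) as multi-page TIFF
#'
#' Pages are written green, red, transmitted at 16 bits, the same dialect
#' [read_stack()] reads; round-trips are bit-exact.
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  planes <- lapply(
    list(stack$green, stack$red, stack$transmitted),
    function(p) unclass(p) / 65535
  )
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write the artifacts of a classification run
#'
#' Writes into `outdir`: the two deconvolved planes as 16-bit TIFF, the
#' three overlay masks as RGB PNG (accepted particles coloured, rejected
#' white), the summary table as CSV with rows labelled exactly
#' "6-CF subt Merge", "AnnCy3 subt Merge", "Merge" and columns Count,
#' Total Area, Average Size, %Area, Mean, IntDen, and a JSON run log with
#' the mode, radii, chosen thresholds, gates and deconvolution iteration
#' counts — enough to reproduce the run. All outputs are buffered in memory
#' first, so an unwritable directory fails before anything is lost.
#'
#' @param run An `fc_run` from [classify()].
#' @param outdir Output directory (created if needed).
#' @return Tibble manifest of the files written.
#' @export
write_outputs <- function(run, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outdir, mode = 2) != 0) {
    abort(sprintf("output directory not writable: %s", outdir), class = "fc_io_error")
  }
  paths <- c(
    deconvolved_green = file.path(outdir, "deconvolved_6-CF.tif"),
    deconvolved_red = file.path(outdir, "deconvolved_AnnCy3.tif"),
    overlay_viable = file.path(outdir, "overlay_6-CF_subt_Merge.png"),
    overlay_necrotic = file.path(outdir, "overlay_AnnCy3_subt_Merge.png"),
    overlay_merge = file.path(outdir, "overlay_Merge.png"),
    summary = file.path(outdir, "summary.csv"),
    log = file.path(outdir, "run_log.json")
  )
  write_plane_tiff(run$deconvolved$green, paths["deconvolved_green"])
  write_plane_tiff(run$deconvolved$red, paths["deconvolved_red"])
  png::writePNG(overlay_rgb(run$particles$viable$overlay), paths["overlay_viable"])
  png::writePNG(overlay_rgb(run$particles$necrotic$overlay), paths["overlay_necrotic"])
  png::writePNG(overlay_rgb(run$particles$merge$overlay), paths["overlay_merge"])
  summary <- run$summary
  names(summary) <- c("Image", "Count", "Total Area", "Average Size", "%Area", "Mean", "IntDen")
  utils::write.csv(summary, paths["summary"], row.names = FALSE)
  gates_js <- lapply(run$config$gates, function(g) {
    list(size_min = g$size_min,
         size_max = if (is.finite(g$size_max)) g$size_max else "infinity",
         circ_min = g$circ_min, circ_max = g$circ_max)
  })
  log <- list(
    mode = run$config$mode,
    rolling_radius_green = run$config$rolling_radius_green,
    rolling_radius_red = run$config$rolling_radius_red,
    smooth_passes = run$config$smooth_passes,
    thresholds = run$thresholds,
    gates = gates_js,
    deconvolution = list(
      max_iterations = run$config$deconv$max_iterations,
      termination_change = run$config$deconv$termination_change,
      iterations_green = stage_field(run$stages$green, "deconvolve", "iterations"),
      iterations_red = stage_field(run$stages$red, "deconvolve", "iterations")
    ),
    counts = run$counts,
    source = run$source_path
  )
  jsonlite::write_json(log, paths["log"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tibble(kind = names(paths), path = unname(paths), bytes = file.size(unname(paths)))
}

stage_field <- function(stages, stage, field) {
  for (s in stages) if (identical(s$stage, stage)) return(s[[field]])
  NULL
}

write_plane_tiff <- function(plane, path) {
  bd <- bit_depth(plane)
  tiff::writeTIFF(unclass(plane) / (2^bd - 1), path, bits.per.sample = bd)
  invisible(path)
}

# accepted particles coloured by number, rejected white, background black
overlay_rgb <- function(overlay) {
  h <- nrow(overlay); w <- ncol(overlay)
  rgb <- array(0, c(h, w, 3))
  k <- max(overlay, 0)
  if (k > 0) {
    cols <- grDevices::col2rgb(hcl.colors(max(k, 2), "Spectral")) / 255
    for (ch in 1:3) {
      plane <- matrix(0, h, w)
      pos <- overlay > 0
      plane[pos] <- cols[ch, ((overlay[pos] - 1) %% ncol(cols)) + 1]
      plane[overlay < 0] <- 1 # rejected: white
      rgb[, , ch] <- plane
    }
  } else {
    for (ch in 1:3) rgb[, , ch][overlay < 0] <- 1
  }
  rgb
}
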
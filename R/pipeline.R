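#' Pipeline configuration
#'
#' Bundles every tunable of the classification pipeline. The two presets
#' mirror the validated macro variants: mode `"C"` for control / healthy
#' (green-dominant) samples and mode `"TR"` for treated / dying
#' (red-dominant) samples. The mode fixes the default threshold algorithms
#' (green: intermeans in C, Otsu in TR; red: Triangle in both), the
#' watershed policy (green always; red only in C, since in treated samples
#' the red signal accumulates in punctate foci and does not fuse cells), and
#' the default acceptance gates:
#'
#' | class   | mode C              | mode TR            |
#' |---------|---------------------|--------------------|
#' | merge   | 0.2-1; 100-infinity | 0.1-1; 50-infinity |
#' | red     | 0.3-1; 100-infinity | 0.3-1; 100-infinity|
#' | green   | 0.2-1; 100-infinity | 0.6-1; 100-infinity|
#'
#' The documented size switch between 100 and 50 px^2 is a plain `gates`
#' edit, not a code change.
#'
#' @param mode `"C"` (control) or `"TR"` (treated). Choose by eye: red
#'   signal predominant -> TR; green predominant -> C.
#' @param rolling_radius_green,rolling_radius_red Rolling-ball radii (px).
#' @param optics_green,optics_red [optics_params()] per channel (488 / 561
#'   nm, NA 0.3, air).
#' @param deconv A [deconv_settings()] object.
#' @param gates Named list `merge`, `red_only`, `green_only` of
#'   [gate_params()]; defaults are the mode's validated column above.
#' @param smooth_passes Number of 3x3 mean-smoothing passes (default 2).
#' @param manual_thresholds Optional named list (`green`, `red`) of manual
#'   intensity thresholds overriding the auto algorithms — the escape hatch
#'   for low signal-to-noise images.
#' @param watershed_tolerance Plateau-merging tolerance of the watershed.
#' @return A list of class `fc_config`.
#' @examples
#' cfg <- pipeline_config("TR")
#' cfg$gates$merge$size_min # 50
#' @export
pipeline_config <- function(mode = c("C", "TR"),
                            rolling_radius_green = 50,
                            rolling_radius_red = 30,
                            optics_green = optics_params(488, 0.3),
                            optics_red = optics_params(561, 0.3),
                            deconv = deconv_settings(),
                            gates = NULL,
                            smooth_passes = 2L,
                            manual_thresholds = NULL,
                            watershed_tolerance = 0.5) {
  mode <- match.arg(mode)
  default_gates <- if (mode == "C") {
    list(
      merge = gate_params(100, Inf, 0.2, 1),
      red_only = gate_params(100, Inf, 0.3, 1),
      green_only = gate_params(100, Inf, 0.2, 1)
    )
  } else {
    list(
      merge = gate_params(50, Inf, 0.1, 1),
      red_only = gate_params(100, Inf, 0.3, 1),
      green_only = gate_params(100, Inf, 0.6, 1)
    )
  }
  if (is.null(gates)) gates <- list()
  gates <- utils::modifyList(default_gates, gates)
  stopifnot(all(c("merge", "red_only", "green_only") %in% names(gates)))
  structure(
    list(
      mode = mode,
      rolling_radius_green = rolling_radius_green,
      rolling_radius_red = rolling_radius_red,
      optics_green = optics_green, optics_red = optics_red,
      deconv = deconv, gates = gates,
      smooth_passes = as.integer(smooth_passes),
      manual_thresholds = manual_thresholds,
      watershed_tolerance = watershed_tolerance
    ),
    class = "fc_config"
  )
}

threshold_algorithm_for <- function(channel, mode) {
  if (channel == "green") {
    if (mode == "C") "default" else "otsu"
  } else {
    "triangle"
  }
}

use_watershed_for <- function(channel, mode) {
  channel == "green" || mode == "C"
}

#' Process one channel into a binary mask
#'
#' The ordered per-channel stages: (1) rolling-ball background subtraction
#' with the channel's radius; (2) Richardson-Lucy deconvolution with the
#' channel's diffraction PSF; (3) `smooth_passes` rounds of 3x3 mean
#' smoothing; (4) auto-thresholding — green: intermeans in mode C, Otsu in
#' mode TR; red: Triangle in both — unless a manual threshold overrides;
#' (5) binarisation (bright foreground); (6) watershed separation for green
#' in both modes and for red in mode C only. A stage log (names, parameters,
#' chosen threshold, deconvolution iterations) is attached as attribute
#' `stages`; the deconvolved plane as attribute `deconvolved`.
#'
#' @param img Image plane.
#' @param channel `"green"` or `"red"`.
#' @param cfg A [pipeline_config()].
#' @return Binary mask with attributes `stages`, `threshold`, `deconvolved`.
#' @export
process_channel <- function(img, channel = c("green", "red"), cfg = pipeline_config()) {
  channel <- match.arg(channel)
  radius <- if (channel == "green") cfg$rolling_radius_green else cfg$rolling_radius_red
  optics <- if (channel == "green") cfg$optics_green else cfg$optics_red
  stages <- list()
  run_stage <- function(name, params, fun) {
    out <- tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' (%s channel) failed: %s", name, channel, conditionMessage(e)),
        class = "fc_stage_error", parent = e
      )
    })
    stages[[length(stages) + 1]] <<- c(list(stage = name), params)
    out
  }
  x <- run_stage("subtract_background", list(radius = radius),
    function() subtract_background(img, radius)
  )
  psf <- generate_psf(optics)
  x <- run_stage("deconvolve",
    list(
      wavelength = optics$wavelength, na = optics$numerical_aperture,
      max_iterations = cfg$deconv$max_iterations
    ),
    function() deconvolve(x, psf, cfg$deconv)
  )
  stages[[length(stages)]]$iterations <- attr(x, "iterations")
  deconvolved <- x
  x <- run_stage("smooth", list(passes = cfg$smooth_passes),
    function() smooth_mean3(x, passes = cfg$smooth_passes)
  )
  manual <- cfg$manual_thresholds[[channel]]
  if (!is.null(manual)) {
    thr <- manual
    algorithm <- "manual"
    stages[[length(stages) + 1]] <- list(stage = "threshold", algorithm = "manual", value = thr)
  } else {
    algorithm <- threshold_algorithm_for(channel, cfg$mode)
    h <- histogram256(x)
    t_bin <- switch(algorithm,
      default = threshold_default(h),
      otsu = threshold_otsu(h),
      triangle = threshold_triangle(h)
    )
    thr <- bin_to_intensity(h, t_bin)
    stages[[length(stages) + 1]] <- list(
      stage = "threshold", algorithm = algorithm, bin = t_bin, value = thr
    )
  }
  mask <- apply_threshold(x, thr)
  if (use_watershed_for(channel, cfg$mode)) {
    mask <- run_stage("watershed", list(tolerance = cfg$watershed_tolerance),
      function() watershed_split(mask, tolerance = cfg$watershed_tolerance)
    )
  }
  attr(mask, "stages") <- stages
  attr(mask, "threshold") <- thr
  attr(mask, "threshold_algorithm") <- algorithm
  attr(mask, "deconvolved") <- deconvolved
  mask
}

#' Classify viable, apoptotic and necrotic cells in a stack
#'
#' The full set-arithmetic classification. With `G` and `R` the processed
#' green and red binary masks:
#' `Merge = G AND R` (double-stained, apoptotic), dilated once to over-cover
#' the halos of apoptotic cells; `Viable = G Subtract dilated-Merge`
#' (green-only); `Necrotic = R Subtract dilated-Merge` (red-only); the
#' dilated Merge is eroded back before counting. Each of the three masks is
#' then counted by gated particle analysis (edge exclusion and hole
#' inclusion on), and
#' `total = viable + apoptotic + necrotic`.
#'
#' @param stack A [channel_stack()] (green, red, transmitted planes).
#' @param cfg A [pipeline_config()].
#' @return Object of class `fc_run`: deconvolved planes, the five masks
#'   (green, red, merge, viable, necrotic), three particle analyses with
#'   overlays, the summary table, thresholds, and `counts`
#'   (viable/apoptotic/necrotic/total). Methods: [tidy.fc_run()],
#'   [glance.fc_run()], [autoplot.fc_run()].
#' @export
classify <- function(stack, cfg = pipeline_config()) {
  check_same_shape(stack$green, stack$red, "green and red planes")
  g <- process_channel(stack$green, "green", cfg)
  r <- process_channel(stack$red, "red", cfg)
  merge <- mask_and(g, r)
  merge_d <- mask_dilate(merge, 1)
  viable <- mask_subtract(g, merge_d)
  necrotic <- mask_subtract(r, merge_d)
  merge_e <- mask_erode(merge_d, 1)
  # the three class masks must be pairwise disjoint by construction
  stopifnot(
    sum(mask_and(viable, necrotic)) == 0,
    sum(mask_and(viable, merge_d)) == 0,
    sum(mask_and(necrotic, merge_d)) == 0
  )
  dg <- attr(g, "deconvolved")
  dr <- attr(r, "deconvolved")
  pa_viable <- analyze_particles(viable, cfg$gates$green_only,
    exclude_edges = TRUE, include_holes = TRUE, reference = dg
  )
  pa_necrotic <- analyze_particles(necrotic, cfg$gates$red_only,
    exclude_edges = TRUE, include_holes = TRUE, reference = dr
  )
  pa_merge <- analyze_particles(merge_e, cfg$gates$merge,
    exclude_edges = TRUE, include_holes = TRUE, reference = dg
  )
  counts <- list(
    viable = pa_viable$summary$count,
    apoptotic = pa_merge$summary$count,
    necrotic = pa_necrotic$summary$count
  )
  counts$total <- total_cells(counts$viable, counts$necrotic, counts$apoptotic)
  summary_rows <- dplyr::bind_rows(
    dplyr::mutate(pa_viable$summary, image = "6-CF subt Merge", .before = 1),
    dplyr::mutate(pa_necrotic$summary, image = "AnnCy3 subt Merge", .before = 1),
    dplyr::mutate(pa_merge$summary, image = "Merge", .before = 1)
  )
  structure(
    list(
      counts = counts,
      summary = summary_rows,
      particles = list(viable = pa_viable, necrotic = pa_necrotic, merge = pa_merge),
      masks = list(green = g, red = r, merge = merge, viable = viable, necrotic = necrotic),
      deconvolved = list(green = dg, red = dr),
      thresholds = list(
        green = attr(g, "threshold"), red = attr(r, "threshold"),
        green_algorithm = attr(g, "threshold_algorithm"),
        red_algorithm = attr(r, "threshold_algorithm")
      ),
      stages = list(green = attr(g, "stages"), red = attr(r, "stages")),
      config = cfg,
      source_path = stack$source_path
    ),
    class = "fc_run"
  )
}

#' Total cell count
#'
#' The headline total: green-only (viable) + red-only (necrotic) +
#' double-stained (apoptotic) counts.
#'
#' @param viable,necrotic,apoptotic Non-negative counts.
#' @return Their sum.
#' @examples
#' total_cells(316, 3, 5) # 324
#' @export
total_cells <- function(viable, necrotic, apoptotic) {
  if (any(c(viable, necrotic, apoptotic) < 0)) {
    abort("counts must be non-negative.", class = "fc_invalid_parameter")
  }
  viable + necrotic + apoptotic
}

#' @export
print.fc_run <- function(x, ...) {
  cat("<classification run>\n")
  cat(sprintf(
    "  mode %s | thresholds: green %.1f (%s), red %.1f (%s)\n",
    x$config$mode, x$thresholds$green, x$thresholds$green_algorithm,
    x$thresholds$red, x$thresholds$red_algorithm
  ))
  cat(sprintf(
    "  viable %d | apoptotic %d | necrotic %d | total %d\n",
    x$counts$viable, x$counts$apoptotic, x$counts$necrotic, x$counts$total
  ))
  invisible(x)
}

#' Tidy a classification run
#'
#' `tidy()` returns one row per cell class with its count and summary
#' statistics; `glance()` returns a one-row overview of the run.
#'
#' @param x An `fc_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fc_run <- function(x, ...) {
  cls <- tibble(
    image = c("6-CF subt Merge", "AnnCy3 subt Merge", "Merge"),
    class = c("viable", "necrotic", "apoptotic")
  )
  dplyr::left_join(cls, x$summary, by = "image")
}

#' @rdname tidy.fc_run
#' @export
glance.fc_run <- function(x, ...) {
  tibble(
    mode = x$config$mode,
    viable = x$counts$viable, apoptotic = x$counts$apoptotic,
    necrotic = x$counts$necrotic, total = x$counts$total,
    threshold_green = x$thresholds$green, threshold_red = x$thresholds$red,
    algorithm_green = x$thresholds$green_algorithm,
    algorithm_red = x$thresholds$red_algorithm
  )
}
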
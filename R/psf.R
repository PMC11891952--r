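#' Optical parameters of the imaging system
#'
#' Bundles the quantities needed to model the microscope's diffraction
#' pattern: medium refractive index (1.0 for an air objective), numerical
#' aperture (0.3 for the validated 10x objective), excitation wavelength in
#' nm (488 for the green 6-CF channel, 561 for red AnnCy3), the lateral
#' pixel spacing in nm/px, and the side length of the synthesised PSF image.
#'
#' `pixel_spacing` is a calibration the user must supply for their own data;
#' the default of 25 nm is a documented calibration placeholder only.
#'
#' @param wavelength Wavelength in nm, within `[300, 800]`.
#' @param numerical_aperture Dimensionless, `0 < NA < refractive_index`.
#' @param refractive_index Dimensionless, at most 2.
#' @param pixel_spacing nm per pixel, > 0.
#' @param psf_size Side of the square PSF image in px; odd, >= 15.
#' @return A list of class `fc_optics`.
#' @examples
#' optics_params(488, 0.3, pixel_spacing = 25)
#' @export
optics_params <- function(wavelength, numerical_aperture = 0.3,
                          refractive_index = 1.0, pixel_spacing = 25,
                          psf_size = 63L) {
  if (!(numerical_aperture > 0 && numerical_aperture < refractive_index &&
        refractive_index <= 2)) {
    abort("need 0 < numerical_aperture < refractive_index <= 2.",
      class = "fc_invalid_parameter"
    )
  }
  if (wavelength < 300 || wavelength > 800) {
    abort("`wavelength` must be in [300, 800] nm.", class = "fc_invalid_parameter")
  }
  if (pixel_spacing <= 0) {
    abort("`pixel_spacing` must be > 0.", class = "fc_invalid_parameter")
  }
  structure(
    list(
      wavelength = wavelength, numerical_aperture = numerical_aperture,
      refractive_index = refractive_index, pixel_spacing = pixel_spacing,
      psf_size = as.integer(psf_size)
    ),
    class = "fc_optics"
  )
}

#' Lateral Rayleigh resolution in pixels
#'
#' The Rayleigh criterion distance `0.61 * wavelength / NA`, expressed in
#' pixels by dividing by the pixel spacing.
#'
#' @param optics An [optics_params()] object.
#' @return Resolution in pixels (real).
#' @export
rayleigh_resolution_px <- function(optics) {
  0.61 * optics$wavelength / optics$numerical_aperture / optics$pixel_spacing
}

#' Diffraction-limited in-focus PSF
#'
#' The Airy intensity pattern `I(r) = (2 J1(v) / v)^2` with
#' `v = 2 * pi * NA * r * pixel_spacing / wavelength` (J1 the first-order
#' Bessel function of the first kind), sampled at pixel centres on a square
#' odd-sized grid and normalised to unit sum. The first dark ring falls at
#' the Rayleigh radius `0.61 * lambda / (NA * pixel_spacing)` px.
#'
#' @param optics An [optics_params()] object; `psf_size` must be odd and
#'   >= 15.
#' @return Image plane whose pixels sum to 1 (class `fc_psf`/`fc_plane`).
#' @export
generate_psf <- function(optics) {
  n <- optics$psf_size
  if (n %% 2 == 0 || n < 15) {
    abort("`psf_size` must be odd and >= 15.", class = "fc_invalid_parameter")
  }
  c0 <- (n + 1) / 2
  idx <- seq_len(n) - c0
  r <- sqrt(outer(idx^2, idx^2, "+"))
  v <- 2 * pi * optics$numerical_aperture * r * optics$pixel_spacing /
    optics$wavelength
  airy <- function(v) ifelse(v == 0, 1, (2 * besselJ(v, 1) / v)^2)
  px <- airy(v)
  px <- px / sum(px)
  structure(px, bit_depth = 16L, class = c("fc_psf", "fc_plane", "matrix", "array"))
}

#' Average-intensity z-projection
#'
#' Pixelwise arithmetic mean across a stack of equally shaped planes; the
#' route used to reduce a 3-D PSF stack to the 2-D kernel used here.
#'
#' @param stack A list of image planes of identical shape (>= 1).
#' @return Image plane (the mean).
#' @export
zproject_average <- function(stack) {
  if (!is.list(stack) || length(stack) == 0) {
    abort("`stack` must be a non-empty list of planes.", class = "fc_invalid_input")
  }
  for (p in stack) check_same_shape(stack[[1]], p, "stack planes")
  acc <- Reduce(`+`, lapply(stack, unclass))
  replane(acc / length(stack), stack[[1]])
}

#' Deconvolution settings
#'
#' Defaults follow the validated configuration: no Wiener regularisation
#' (`wiener_gamma = 0`), unit low-pass in x/y, at most 10 iterations,
#' stopping when the relative L2 change between successive estimates falls
#' below 0.010. `lowpass_z` is accepted for configuration compatibility and
#' ignored (processing is 2-D).
#'
#' @param wiener_gamma Tikhonov-style damping, >= 0; 0 disables it.
#' @param lowpass_xy Low-pass filter diameter in px applied to the running
#'   estimate each iteration; a diameter of 1 px covers a single pixel, so
#'   the default 1.0 (and anything smaller) applies no filtering.
#' @param lowpass_z Ignored (2-D processing).
#' @param max_iterations Iteration cap, >= 1.
#' @param termination_change Relative-change stopping fraction in `[0, 1)`.
#' @return A list of class `fc_deconv_settings`.
#' @export
deconv_settings <- function(wiener_gamma = 0, lowpass_xy = 1, lowpass_z = 1,
                            max_iterations = 10L, termination_change = 0.010) {
  if (max_iterations < 1) abort("`max_iterations` must be >= 1.", class = "fc_invalid_parameter")
  if (termination_change < 0 || termination_change >= 1) {
    abort("`termination_change` must be in [0, 1).", class = "fc_invalid_parameter")
  }
  structure(
    list(
      wiener_gamma = wiener_gamma, lowpass_xy = lowpass_xy,
      lowpass_z = lowpass_z, max_iterations = as.integer(max_iterations),
      termination_change = termination_change
    ),
    class = "fc_deconv_settings"
  )
}

#' Iterative Richardson-Lucy deconvolution
#'
#' Non-negativity-constrained Richardson-Lucy restoration
#' `x_{k+1} = x_k / (1 + gamma) * (K' (*) (d / (K (*) x_k)))`, where `(*)`
#' denotes FFT-based convolution with replicated borders, `K'` the flipped
#' PSF, and `gamma` the optional Tikhonov-style damping (`wiener_gamma`;
#' 0 gives plain Richardson-Lucy). Iteration stops after
#' `settings$max_iterations` or as soon as the relative L2 change
#' `||x_k - x_{k-1}|| / ||x_{k-1}||` drops below
#' `settings$termination_change`. The result is clipped to the input's bit
#' range; the number of iterations performed is attached as attribute
#' `iterations`.
#'
#' @param img Image plane to restore.
#' @param psf Normalised PSF (sums to 1), no larger than the image.
#' @param settings A [deconv_settings()] object.
#' @return Restored image plane with attribute `iterations`.
#' @export
deconvolve <- function(img, psf, settings = deconv_settings()) {
  px <- unclass(img) * 1.0
  k <- unclass(psf)
  if (nrow(k) > nrow(px) || ncol(k) > ncol(px)) {
    abort("PSF must not be larger than the image.", class = "fc_invalid_input")
  }
  if (abs(sum(k) - 1) > 1e-6) {
    abort("PSF must be normalised to unit sum.", class = "fc_invalid_input")
  }
  kf <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
  plan_k <- conv_plan(k, dim(px))
  plan_kf <- conv_plan(kf, dim(px))
  # low-pass diameter of 1 px covers a single pixel: a no-op
  plan_lp <- NULL
  if (!is.null(settings$lowpass_xy) && settings$lowpass_xy > 1) {
    sigma <- settings$lowpass_xy / 2
    r <- ceiling(2 * sigma)
    g <- exp(-(-r:r)^2 / (2 * sigma^2))
    lp <- outer(g, g); lp <- lp / sum(lp)
    plan_lp <- conv_plan(lp, dim(px))
  }
  eps <- 1e-12
  gamma <- settings$wiener_gamma
  x <- px
  iters <- 0L
  for (i in seq_len(settings$max_iterations)) {
    blurred <- conv_apply(x, plan_k)
    ratio <- px / pmax(blurred, eps)
    x_new <- x / (1 + gamma) * conv_apply(ratio, plan_kf)
    x_new <- pmax(x_new, 0)
    if (!is.null(plan_lp)) x_new <- conv_apply(x_new, plan_lp)
    iters <- i
    denom <- sqrt(sum(x^2))
    change <- if (denom == 0) 0 else sqrt(sum((x_new - x)^2)) / denom
    x <- x_new
    if (change < settings$termination_change) break
  }
  out <- pmin(pmax(x, 0), 2^bit_depth(img) - 1)
  out <- replane(out, img)
  attr(out, "iterations") <- iters
  out
}

# FFT convolution with replicated borders. The kernel transform is computed
# once per deconvolution run; canvases are padded to 7-smooth sizes, where
# R's mixed-radix FFT is fast.
conv_plan <- function(kern, dims) {
  ry <- (nrow(kern) - 1) %/% 2
  rx <- (ncol(kern) - 1) %/% 2
  n1 <- good_fft_size(dims[1] + 2 * ry)
  n2 <- good_fft_size(dims[2] + 2 * rx)
  kpad <- matrix(0, n1, n2)
  cy <- ry + 1; cx <- rx + 1
  for (i in seq_len(nrow(kern))) {
    ti <- ((i - cy) %% n1) + 1
    tj <- ((seq_len(ncol(kern)) - cx) %% n2) + 1
    kpad[ti, tj] <- kern[i, ]
  }
  list(K = fft(kpad), ry = ry, rx = rx, n1 = n1, n2 = n2, h = dims[1], w = dims[2])
}

conv_apply <- function(x, plan) {
  h <- plan$h; w <- plan$w; ry <- plan$ry; rx <- plan$rx
  pad <- matrix(0, plan$n1, plan$n2)
  yi <- pmin(pmax(seq_len(h + 2 * ry) - ry, 1), h)
  xi <- pmin(pmax(seq_len(w + 2 * rx) - rx, 1), w)
  pad[seq_along(yi), seq_along(xi)] <- x[yi, xi]
  y <- Re(fft(fft(pad) * plan$K, inverse = TRUE)) / (plan$n1 * plan$n2)
  y[(ry + 1):(ry + h), (rx + 1):(rx + w)]
}

good_fft_size <- function(n) {
  is_smooth <- function(m) {
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    m == 1
  }
  while (!is_smooth(n)) n <- n + 1
  n
}
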
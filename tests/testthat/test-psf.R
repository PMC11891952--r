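test_that("Rayleigh resolution follows 0.61 lambda / (NA * pixel spacing)", {
  o <- optics_params(488, 0.3, pixel_spacing = 150)
  expect_equal(rayleigh_resolution_px(o), 0.61 * 488 / 0.3 / 150)
  # doubling NA at fixed wavelength and spacing halves the value
  o2 <- optics_params(488, 0.6, pixel_spacing = 150)
  expect_equal(rayleigh_resolution_px(o2), rayleigh_resolution_px(o) / 2)
  # linear in wavelength, inverse in spacing
  expect_equal(
    rayleigh_resolution_px(optics_params(600, 0.3, pixel_spacing = 150)) /
      rayleigh_resolution_px(o),
    600 / 488
  )
  expect_equal(
    rayleigh_resolution_px(optics_params(488, 0.3, pixel_spacing = 300)),
    rayleigh_resolution_px(o) / 2
  )
  expect_error(optics_params(488, 0.3, pixel_spacing = 0), class = "fc_invalid_parameter")
  expect_error(optics_params(488, 1.2, refractive_index = 1), class = "fc_invalid_parameter")
})

test_that("the generated PSF is a normalised Airy pattern", {
  o <- optics_params(488, 0.3, pixel_spacing = 150, psf_size = 63)
  psf <- generate_psf(o)
  expect_equal(sum(psf), 1, tolerance = 1e-12)
  centre <- 32
  expect_equal(which.max(psf), (centre - 1) * 63 + centre) # centre is the global max
  # first dark ring along the +x radial profile at the Rayleigh radius
  profile <- psf[centre, centre:63]
  local_min <- which(diff(sign(diff(profile))) > 0)[1] + 1
  expect_equal(local_min - 1, rayleigh_resolution_px(o), tolerance = 1)
  # four-fold rotational symmetry
  m <- matrix(unclass(psf), 63, 63)
  expect_equal(m, t(m), tolerance = 1e-9)
  expect_equal(m, m[63:1, ], tolerance = 1e-9)
  expect_error(generate_psf(optics_params(488, 0.3, psf_size = 64)),
    class = "fc_invalid_parameter"
  )
})

test_that("average z-projection equals the per-pixel mean", {
  one <- image_plane(matrix(4, 6, 6), 8)
  expect_equal(unclass(zproject_average(list(one))), unclass(one))
  two <- zproject_average(list(
    image_plane(matrix(10, 6, 6), 8), image_plane(matrix(30, 6, 6), 8)
  ))
  expect_true(all(two == 20))
  set.seed(21)
  stack <- lapply(1:5, function(i) image_plane(matrix(runif(36, 0, 255), 6, 6), 8))
  proj <- zproject_average(stack)
  for (y in 1:6) for (x in 1:6) {
    expect_equal(proj[y, x], mean(sapply(stack, function(p) p[y, x])))
  }
  expect_error(zproject_average(list()), class = "fc_invalid_input")
})

test_that("deconvolution is exact for a delta kernel and sharpens blurred points", {
  delta <- matrix(0, 15, 15); delta[8, 8] <- 1
  set.seed(31)
  img <- image_plane(matrix(runif(900, 0, 60000), 30, 30), 16)
  for (iters in c(1, 4, 10)) {
    out <- deconvolve(img, delta, deconv_settings(max_iterations = iters,
      termination_change = 0))
    expect_equal(unclass(out), unclass(img), ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(attr(out, "iterations"), iters)
  }

  # blur a point source with the PSF, deconvolve, and require the
  # peak-to-total-energy ratio to increase
  o <- optics_params(488, 0.3, pixel_spacing = 300, psf_size = 31)
  psf <- generate_psf(o)
  point <- matrix(0, 64, 64); point[32, 32] <- 10000
  blurred <- fluorcount:::conv_apply(point, fluorcount:::conv_plan(unclass(psf), dim(point)))
  blurred_img <- image_plane(pmax(blurred, 0), 16)
  restored <- deconvolve(blurred_img, psf, deconv_settings(max_iterations = 10,
    termination_change = 0))
  ratio <- function(m) max(m) / sum(m)
  expect_gt(ratio(unclass(restored)), ratio(unclass(blurred_img)))

  big <- matrix(0, 5, 5); big[3, 3] <- 1
  expect_error(deconvolve(image_plane(matrix(1, 3, 3), 8), big),
    class = "fc_invalid_input"
  )
  expect_error(
    deconvolve(img, matrix(0.3, 3, 3)), # kernel sum != 1
    class = "fc_invalid_input"
  )
})

test_that("iteration stops at the configured relative-change threshold", {
  o <- optics_params(488, 0.3, pixel_spacing = 300, psf_size = 31)
  psf <- generate_psf(o)
  set.seed(8)
  scene <- matrix(200, 48, 48)
  scene[20:28, 20:28] <- 30000
  img <- image_plane(scene, 16)
  # successive estimates from capped runs give the exact change sequence
  est <- lapply(1:6, function(k) {
    unclass(deconvolve(img, psf, deconv_settings(max_iterations = k,
      termination_change = 0)))
  })
  changes <- sapply(2:6, function(k) {
    sqrt(sum((est[[k]] - est[[k - 1]])^2)) / sqrt(sum(est[[k - 1]]^2))
  })
  tau <- changes[2] * 1.01 # threshold crossed exactly at iteration 3
  expected_stop <- 1 + which(changes < tau)[1]
  out <- deconvolve(img, psf, deconv_settings(max_iterations = 10,
    termination_change = tau))
  expect_equal(attr(out, "iterations"), expected_stop)
})

test_that("deconvolution conserves energy when nothing clips", {
  o <- optics_params(488, 0.3, pixel_spacing = 300, psf_size = 31)
  psf <- generate_psf(o)
  blob <- matrix(0, 96, 96)
  blob[40:56, 40:56] <- 20000
  blurred <- fluorcount:::conv_apply(blob, fluorcount:::conv_plan(unclass(psf), dim(blob)))
  img <- image_plane(pmax(blurred, 0), 16)
  out <- deconvolve(img, psf, deconv_settings(max_iterations = 10, termination_change = 0))
  expect_lt(abs(sum(out) - sum(img)) / sum(img), 0.05)
})
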
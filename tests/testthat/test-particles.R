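test_that("component labelling is 8-connected in raster order", {
  empty <- binary_mask(matrix(0L, 8, 8))
  expect_equal(attr(label_components(empty), "n_components"), 0)

  two <- matrix(0L, 10, 10)
  two[2:3, 2:3] <- 1L   # first in raster order
  two[6:8, 6:8] <- 1L
  lab <- label_components(binary_mask(two))
  expect_equal(attr(lab, "n_components"), 2)
  expect_equal(unique(as.vector(lab[2:3, 2:3])), 1L)
  expect_equal(unique(as.vector(lab[6:8, 6:8])), 2L)

  diag2 <- matrix(0L, 5, 5)
  diag2[2, 2] <- 1L; diag2[3, 3] <- 1L # touching only diagonally
  expect_equal(attr(label_components(binary_mask(diag2)), "n_components"), 1)

  for (s in 1:5) {
    m <- random_blob_mask(20, 20, n_seeds = 4, grow = 2, seed = s + 40)
    lab <- unclass(label_components(binary_mask(m)))
    ref <- oracle_components(m)
    expect_equal(max(lab), max(ref))
    # identical component membership (same partition of foreground)
    expect_equal(lab > 0, ref > 0)
    for (i in seq_len(max(ref))) {
      expect_equal(length(unique(lab[ref == i])), 1)
    }
  }
})

test_that("particle measurements match closed forms", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  rec <- measure_particle(label_components(binary_mask(sq)), 1)
  expect_equal(rec$area, 100)
  expect_equal(rec$perimeter, 40)
  expect_equal(rec$circularity, 4 * pi * 100 / 1600)

  line <- matrix(0L, 6, 20); line[3, 5:14] <- 1L
  rl <- measure_particle(label_components(binary_mask(line)), 1)
  expect_equal(rl$area, 10)
  expect_equal(rl$perimeter, 22)
  expect_equal(rl$circularity, 4 * pi * 10 / 22^2, tolerance = 1e-12)
  expect_lt(rl$circularity, 0.6) # below the treated-mode green gate

  disk <- make_disk_mask(51, 51, 26, 26, 20)
  rd <- measure_particle(label_components(disk), 1)
  expect_gte(rd$circularity, 0.9)
  expect_lte(rd$circularity, 1.0)

  # circularity of rasterised disks approaches 1 with radius and never exceeds it
  circs <- sapply(c(10, 20, 40), function(r) {
    m <- make_disk_mask(2 * r + 11, 2 * r + 11, r + 6, r + 6, r)
    measure_particle(label_components(m), 1)$circularity
  })
  expect_true(all(diff(circs) > 0))
  expect_true(all(circs <= 1))

  expect_error(measure_particle(label_components(disk), 99), class = "fc_not_found")
})

test_that("hole inclusion and intensity statistics behave as documented", {
  ring <- mask_subtract(
    make_disk_mask(31, 31, 16, 16, 10),
    make_disk_mask(31, 31, 16, 16, 5)
  )
  lab <- label_components(ring)
  with_holes <- measure_particle(lab, 1, include_holes = TRUE)
  without <- measure_particle(lab, 1, include_holes = FALSE)
  expect_equal(with_holes$area, sum(make_disk_mask(31, 31, 16, 16, 10)))
  expect_lt(without$area, with_holes$area)

  ref <- image_plane(matrix(7, 31, 31), 8)
  rec <- measure_particle(lab, 1, reference = ref)
  expect_equal(rec$mean_intensity, 7)
  expect_equal(rec$integrated_density, 7 * rec$area)
})

test_that("gating, edge exclusion and overlays follow the acceptance rules", {
  canvas <- matrix(0L, 40, 130)
  canvas[10:19, 10:19] <- 1L    # 10x10 square: area 100, circ 0.785
  canvas[25, 10:109] <- 1L      # 1x100 line: area 100, circ ~0.15
  sq_line <- binary_mask(canvas)

  # validated control gate: circ 0.2-1, size 100-inf -> square passes
  res <- analyze_particles(sq_line, gate_params(100, Inf, 0.2, 1))
  expect_equal(res$summary$count, 1)
  # treated-mode green gate: circ 0.6-1 rejects the line, accepts the square
  res2 <- analyze_particles(sq_line, gate_params(100, Inf, 0.6, 1))
  expect_equal(res2$summary$count, 1)
  expect_false(res2$records$accepted[res2$records$circularity < 0.6])

  # edge exclusion
  edge <- matrix(0L, 20, 20); edge[1:10, 5:14] <- 1L # touches row 1
  expect_equal(analyze_particles(binary_mask(edge), gate_params(), exclude_edges = TRUE)$summary$count, 0)
  expect_equal(analyze_particles(binary_mask(edge), gate_params(), exclude_edges = FALSE)$summary$count, 1)

  # relaxing a gate never decreases the count
  set.seed(13)
  m <- random_blob_mask(48, 48, n_seeds = 6, grow = 3, seed = 99)
  tight <- analyze_particles(binary_mask(m), gate_params(40, 200, 0.5, 1), exclude_edges = FALSE)
  loose <- analyze_particles(binary_mask(m), gate_params(10, Inf, 0.1, 1), exclude_edges = FALSE)
  expect_gte(loose$summary$count, tight$summary$count)

  # conservation: total area, average size, percent area
  acc <- loose$records[loose$records$accepted, ]
  expect_equal(loose$summary$total_area, sum(acc$area))
  expect_equal(loose$summary$average_size * loose$summary$count, loose$summary$total_area)
  expect_equal(loose$summary$percent_area, 100 * sum(acc$area) / (48 * 48))

  # overlay: exactly `count` numbered objects, rejected drawn as -1
  ov <- res2$overlay
  expect_equal(sort(unique(ov[ov > 0])), seq_len(res2$summary$count))
  expect_true(all(res2$records$number[res2$records$accepted] == seq_len(res2$summary$count)))

  expect_error(
    analyze_particles(sq_line, gate_params(), reference = image_plane(matrix(0, 5, 5), 8)),
    class = "fc_invalid_input"
  )
  expect_error(gate_params(circ_min = 0.5, circ_max = 0.2), class = "fc_invalid_parameter")
})
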
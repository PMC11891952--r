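random_histogram <- function(seed, n_bins = 20) {
  set.seed(seed)
  counts <- integer(256)
  support <- sort(sample(0:255, n_bins))
  counts[support + 1] <- rpois(n_bins, 50) + 1L
  counts
}

hist_from_counts <- function(counts) {
  structure(
    list(counts = counts, offset = 0, bin_width = 1, source_bit_depth = 8L),
    class = "fc_hist256"
  )
}

test_that("histogram256 bins 8-bit directly and min-max scales deeper data", {
  zeros <- image_plane(matrix(0, 10, 10), 8)
  h <- histogram256(zeros)
  expect_equal(h$counts[1], 100)
  expect_equal(sum(h$counts), 100)

  two <- image_plane(matrix(c(0, 255), 10, 10), 8)
  h2 <- histogram256(two)
  expect_equal(h2$counts[c(1, 256)], c(50, 50))
  expect_equal(sum(h2$counts > 0), 2)

  set.seed(5)
  px <- matrix(sample(3000:42000, 400, replace = TRUE), 20, 20)
  h3 <- histogram256(image_plane(px, 16))
  # direct scaling-loop oracle
  lo <- min(px); width <- (max(px) - lo) / 256
  expected <- integer(256)
  for (v in as.vector(px)) {
    b <- min(floor((v - lo) / width), 255)
    expected[b + 1] <- expected[b + 1] + 1L
  }
  expect_equal(h3$counts, expected)
})

test_that("Otsu equals the exhaustive between-class-variance maximiser", {
  spikes <- integer(256); spikes[c(51, 201)] <- 100L
  h <- hist_from_counts(spikes)
  expect_equal(threshold_otsu(h), oracle_otsu(spikes))
  expect_equal(threshold_otsu(h), 50) # lowest qualifying index of the tie

  one <- integer(256); one[43] <- 10L
  expect_equal(threshold_otsu(hist_from_counts(one)), 42)

  for (s in 1:50) {
    counts <- random_histogram(s)
    expect_equal(threshold_otsu(hist_from_counts(counts)), oracle_otsu(counts))
  }
})

test_that("intermeans threshold reaches the stated fixed point", {
  spikes <- integer(256); spikes[c(51, 201)] <- 100L
  expect_equal(threshold_default(hist_from_counts(spikes)), 125)

  # bimodal mixture: returned t satisfies t = round((mu_low + mu_high) / 2)
  set.seed(9)
  counts <- integer(256)
  low <- table(pmin(pmax(round(rnorm(4000, 60, 12)), 0), 255))
  high <- table(pmin(pmax(round(rnorm(2500, 190, 15)), 0), 255))
  counts[as.integer(names(low)) + 1] <- counts[as.integer(names(low)) + 1] + as.integer(low)
  counts[as.integer(names(high)) + 1] <- counts[as.integer(names(high)) + 1] + as.integer(high)
  t <- threshold_default(hist_from_counts(counts))
  lev <- 0:255
  mu_low <- sum(counts[1:(t + 1)] * lev[1:(t + 1)]) / sum(counts[1:(t + 1)])
  mu_high <- sum(counts[(t + 2):256] * lev[(t + 2):256]) / sum(counts[(t + 2):256])
  expect_equal(t, round((mu_low + mu_high) / 2))

  uniform <- rep(10L, 256)
  expect_equal(threshold_default(hist_from_counts(uniform)), oracle_isodata(uniform))
  expect_true(threshold_default(hist_from_counts(uniform)) %in% c(127L, 128L))
})

test_that("triangle threshold equals the exhaustive distance scan", {
  # spike with a long exponential right tail
  counts <- integer(256)
  counts[11] <- 2000L
  counts[12:201] <- as.integer(round(1500 * exp(-(1:190) / 40))) + 1L
  h <- hist_from_counts(counts)
  expect_equal(threshold_triangle(h), oracle_triangle(counts))

  # symmetric histogram: mirrored and unmirrored computations agree
  sym <- integer(256)
  sym[101:157] <- c(1:28, 29, 28:1) * 10L # unique central peak
  t_fwd <- oracle_triangle(sym)
  t_rev <- 255L - oracle_triangle(rev(sym))
  expect_equal(t_fwd, t_rev)
  expect_equal(threshold_triangle(hist_from_counts(sym)), t_fwd)

  # peak at the right edge forces the mirror path
  edge <- integer(256)
  edge[256] <- 3000L
  edge[60:255] <- pmax(edge[60:255], as.integer(round(2000 * exp((60:255 - 256) / 50))))
  t <- threshold_triangle(hist_from_counts(edge))
  expect_true(t >= 0 && t <= 255)
  expect_equal(t, oracle_triangle(edge))

  for (s in 1:50) {
    counts <- random_histogram(s, n_bins = 40)
    expect_equal(threshold_triangle(hist_from_counts(counts)), oracle_triangle(counts))
  }
})

test_that("thresholds are translation-equivariant on the bin axis", {
  base <- integer(256)
  base[31:90] <- as.integer(round(500 * exp(-((31:90) - 45)^2 / 120))) + 2L
  base[121:150] <- 40L
  for (k in c(10L, 40L)) {
    shifted <- integer(256)
    shifted[(31:150) + k] <- base[31:150]
    expect_equal(
      threshold_otsu(hist_from_counts(shifted)),
      threshold_otsu(hist_from_counts(base)) + k
    )
    expect_equal(
      threshold_triangle(hist_from_counts(shifted)),
      threshold_triangle(hist_from_counts(base)) + k
    )
    expect_equal(
      threshold_default(hist_from_counts(shifted)),
      threshold_default(hist_from_counts(base)) + k
    )
  }
})

test_that("apply_threshold selects strictly brighter pixels", {
  set.seed(3)
  px <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  img <- image_plane(px, 8)
  expect_equal(sum(apply_threshold(img, max(px))), 0)
  expect_equal(sum(apply_threshold(img, -1)), 400)
  t <- 130
  expect_equal(sum(apply_threshold(img, t)), sum(px > t))
})
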
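test_that("bpp arithmetic and monotonicity", {
  expect_equal(bpp(100, c(20, 20)), 2.0)
  expect_lt(bpp(100, c(20, 20)), bpp(150, c(20, 20)))
  m <- random_model()
  img <- generate_image("smooth", 20, 20, seed = 1)
  bytes <- compress(img, m, route_plan("fast"))
  # consistent with on-disk size
  f <- tempfile()
  writeBin(bytes, f)
  expect_equal(bpp(bytes), 8 * file.size(f) / 400)
  unlink(f)
})

test_that("probability heatmap indexes the volume at the observed residual", {
  h <- 4; w <- 5
  res <- matrix(sample(0:510, h * w, replace = TRUE), h, w)
  perfect <- array(0, c(h, w, 511))
  for (i in 1:h) for (j in 1:w) perfect[i, j, res[i, j] + 1] <- 1
  expect_true(all(probability_heatmap(res, perfect) == 1))

  unif <- array(1 / 511, c(h, w, 511))
  expect_true(all(abs(probability_heatmap(res, unif) - 1 / 511) < 1e-12))

  set.seed(41)
  a <- array(rexp(h * w * 511), c(h, w, 511))
  prob <- a / array(rep(apply(a, c(1, 2), sum), 511), dim(a))
  hm <- probability_heatmap(res, prob)
  for (k in 1:5) {
    i <- sample(h, 1); j <- sample(w, 1)
    expect_equal(hm[i, j], prob[i, j, res[i, j] + 1])
  }
})

test_that("probability bins use the closed middle interval and sum to 100", {
  all_ones <- matrix(1, 3, 3)
  b <- probability_bins(all_ones)
  expect_equal(c(b$frac_high, b$frac_mid, b$frac_low), c(100, 0, 0))

  unif <- matrix(1 / 511, 3, 3)
  b2 <- probability_bins(unif)
  expect_equal(c(b2$frac_high, b2$frac_mid, b2$frac_low), c(0, 0, 100))

  # hand-built map: boundary values 0.01 and 0.1 belong to the middle bin
  hm <- matrix(c(0.5, 0.1, 0.01, 0.005), 2, 2)
  b3 <- probability_bins(hm)
  expect_equal(b3$frac_high, 25)
  expect_equal(b3$frac_mid, 50)
  expect_equal(b3$frac_low, 25)
  expect_equal(b3$frac_high + b3$frac_mid + b3$frac_low, 100, tolerance = 1e-4)

  # scope excludes masked pixels
  sc <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  b4 <- probability_bins(hm, sc)
  expect_equal(b4$n, 2L)
  expect_equal(b4$frac_high, 50)
})

test_that("Shannon accounting of a heatmap tracks the coded chunk length", {
  m <- toy_model()
  img <- generate_image("smooth", 32, 32, seed = 6)
  parts <- split_level1(img)
  out <- forward_plane(m, list(parts$a))
  res <- compute_residual(parts$d, out$pred)
  hm <- probability_heatmap(res, out$prob)
  chunk <- tmscodec:::encode_plane_chunk(res, out$prob)
  ideal <- sum(-log2(hm))
  # quantized tables add at most 511/2^16 per class of mass distortion plus
  # termination overhead; the coded size must sit near the Shannon bound
  expect_lte(8 * length(chunk), ideal * 1.1 + 96)
  expect_gte(8 * length(chunk), ideal * 0.9 - 8)
})
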
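test_that("subimage prediction loss matches hand-computed values", {
  y <- matrix(0, 4, 4)
  expect_equal(spl_loss(y, y), 0)
  expect_equal(spl_loss(y, y + 1), 1.0)

  set.seed(31)
  yr <- matrix(sample(0:255, 16), 4, 4)
  ph <- matrix(runif(16, 0, 255), 4, 4)
  # odd-column scope: 0-based odd columns are R columns 2 and 4 (8 pixels)
  hand <- sum(abs(yr[, c(2, 4)] - ph[, c(2, 4)])) / 8
  expect_equal(spl_loss(yr, ph, "odd-columns"), hand)
  expect_equal(spl_loss(yr, ph, "all"), mean(abs(yr - ph)))
})

test_that("probability prediction loss matches the brute-force double sum", {
  h <- 3; w <- 4
  res <- matrix(sample(0:510, h * w, replace = TRUE), h, w)
  # perfect one-hot model: loss exactly 0
  perfect <- array(0, c(h, w, 511))
  for (i in 1:h) for (j in 1:w) perfect[i, j, res[i, j] + 1] <- 1
  expect_equal(ppl_loss(res, perfect), 0)

  # uniform model: exactly ln(511) per pixel
  unif <- array(1 / 511, c(h, w, 511))
  expect_equal(ppl_loss(res, unif), log(511))

  set.seed(32)
  a <- array(rexp(h * w * 511), c(h, w, 511))
  prob <- a / array(rep(apply(a, c(1, 2), sum), 511), dim(a))
  w_all <- matrix(1, h, w)
  expect_equal(ppl_loss(res, prob), ppl_oracle(res, prob, w_all),
               tolerance = 1e-6)
  w_odd <- w_all; w_odd[, c(1, 3)] <- 0
  expect_equal(ppl_loss(res, prob, "odd-columns"),
               ppl_oracle(res, prob, w_odd), tolerance = 1e-6)
})

test_that("tape losses equal the plain loss functions", {
  set.seed(33)
  y <- matrix(sample(0:255, 36), 6, 6)
  yhat <- array(runif(36, 0, 255), c(6, 6, 1))
  w <- matrix(1, 6, 6)
  expect_equal(tmscodec:::ad_mae(NULL, yhat, y, w), spl_loss(y, matrix(yhat, 6, 6)))
  logits <- array(rnorm(6 * 6 * 511), c(6, 6, 511))
  res <- matrix(sample(0:510, 36, replace = TRUE), 6, 6)
  prob <- tmscodec:::softmax_hwk(logits)
  expect_equal(tmscodec:::ad_softmax_ce(NULL, logits, res, w),
               ppl_loss(res, prob), tolerance = 1e-8)
})

test_that("the learning-rate schedule halves every period", {
  cfg <- train_config(lr = 1e-3, lr_halving_period = 500)
  expect_equal(lr_at_epoch(cfg, 1), 1e-3)
  expect_equal(lr_at_epoch(cfg, 500), 1e-3)
  expect_equal(lr_at_epoch(cfg, 501), 5e-4)
  expect_equal(lr_at_epoch(cfg, 1001), 2.5e-4)
  expect_equal(lr_at_epoch(cfg, 2000), 1.25e-4)
})

test_that("a few optimization steps reduce the loss reproducibly", {
  imgs <- generate_dataset(4, "smooth", seed = 55, height = 32, width = 32)
  cfg <- train_config(crop_size = 16, batch_size = 1, epochs = 3, seed = 77)
  m0 <- codec_model(test_config(), seed = 13)
  m1 <- train_codec(m0, imgs, cfg)
  h1 <- m1$history
  expect_equal(nrow(h1), 12L)
  expect_lt(mean(tail(h1$loss, 4)), mean(head(h1$loss, 4)))
  # fixed seed: identical trajectory
  m2 <- train_codec(m0, imgs, cfg)
  expect_identical(m2$history$loss, h1$loss)
  expect_identical(m2$plane, m1$plane)
})
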
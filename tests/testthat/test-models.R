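test_that("SE attention matches a straight-line evaluation of its equations", {
  set.seed(21)
  for (trial in 1:5) {
    C <- 4L
    x <- array(rnorm(2 * 2 * C), c(2, 2, C))
    w1 <- matrix(rnorm(2 * C), 2, C); b1 <- rnorm(2)
    w2 <- matrix(rnorm(C * 2), C, 2); b2 <- rnorm(C)
    z <- ad_gap(NULL, x)
    s <- ad_sigmoid(NULL, ad_dense(NULL,
      ad_relu(NULL, ad_dense(NULL, z, w1, b1)), w2, b2))
    got <- ad_scale_channels(NULL, x, s)
    expect_equal(got, se_oracle(x, w1, b1, w2, b2), tolerance = 1e-6)
    # gating lies in (0,1): attenuation only
    expect_true(all(abs(got) <= abs(x) + 1e-12))
  }
  # constant channel: the squeezed value is that constant
  xc <- array(0, c(3, 5, 2)); xc[, , 1] <- 2.5; xc[, , 2] <- -1
  expect_equal(ad_gap(NULL, xc), c(2.5, -1))
})

test_that("probability head is softmax-normalized for arbitrary weights", {
  for (seed in c(7, 8)) {
    m <- codec_model(test_config(), seed = seed)
    priors <- list(random_plane(18, 14, seed))
    out <- forward_plane(m, priors)
    expect_identical(dim(out$prob), c(18L, 14L, 511L))
    sums <- apply(out$prob, c(1, 2), sum)
    expect_true(max(abs(sums - 1)) < 1e-5)
    expect_true(all(out$prob > 0 & out$prob < 1))
  }
})

test_that("prediction head output is bounded and zero weights give 127.5", {
  m <- random_model()
  out <- forward_plane(m, list(random_plane(16, 16, 1)))
  expect_true(all(out$pred >= 0 & out$pred <= 255))
  expect_identical(dim(out$pred), c(16L, 16L))

  mz <- m
  mz$plane[["pred.w"]][] <- 0
  mz$plane[["pred.b"]][] <- 0
  oz <- forward_plane(mz, list(random_plane(16, 16, 2)))
  expect_true(all(oz$pred == 127.5))
})

test_that("forward passes are shape-stable and bit-reproducible", {
  m <- random_model()
  for (dims in list(c(10L, 12L), c(17L, 9L), c(24L, 24L))) {
    priors <- list(random_plane(dims[1], dims[2], 31),
                   random_plane(dims[1], dims[2], 32))
    o1 <- forward_plane(m, priors)
    o2 <- forward_plane(m, priors)
    expect_identical(o1, o2)
    expect_identical(dim(o1$pred), dims)
    expect_identical(dim(o1$prob), c(dims, 511L))
    left <- random_plane(dims[1], dims[2], 33)
    left[, seq(2, dims[2], by = 2)] <- 0
    r1 <- forward_refine(m, priors, left)
    r2 <- forward_refine(m, priors, left)
    expect_identical(r1, r2)
    expect_identical(dim(r1$pred), dims)
  }
})

test_that("residual identity: zeroed final ResBlock convs pass the skip path", {
  m <- random_model()
  for (i in 1:3) {
    m$plane[[sprintf("res%d.c2.w", i)]][] <- 0
    m$plane[[sprintf("res%d.c2.b", i)]][] <- 0
  }
  xin <- stack_priors(list(random_plane(12, 12, 3)), 3)
  latent <- tmscodec:::resblock_stack(NULL, xin, m$plane)
  stem <- ad_relu(NULL, ad_conv2d(NULL, xin, m$plane[["stem.w"]], m$plane[["stem.b"]]))
  expect_equal(latent, stem, tolerance = 1e-12)
})

test_that("model configuration validates its invariants", {
  expect_error(codec_config(se_reduction = 7), "divide")
  expect_error(codec_config(num_classes = 256), "511")
  cfg <- test_config()
  expect_s3_class(cfg, "codec_config")
  expect_identical(cfg$num_classes, 511L)
})

test_that("checkpoints round-trip through save/load", {
  m <- random_model()
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$plane, m$plane)
  expect_identical(m2$refine, m$refine)
  img <- random_plane(16, 16, 9)
  expect_identical(forward_plane(m, list(img)), forward_plane(m2, list(img)))
  unlink(path)
})

test_that("autodiff gradients agree with finite differences end to end", {
  cfg <- codec_config(base_channels = 2, unet_channels = c(2, 2, 2, 2),
                      se_reduction = 1)
  m <- codec_model(cfg, seed = 1)
  crop <- generate_image("smooth", 16, 16, seed = 2)
  loss_at <- function(model) {
    ad_value(tmscodec:::crop_loss(ad_tape(), model, crop, 1)$loss)
  }
  tape <- ad_tape()
  l <- tmscodec:::crop_loss(tape, m, crop, 1)
  ad_backward(tape, l$loss)
  g <- tmscodec:::collect_param_grads(tape, m)
  set.seed(9)
  for (net in c("plane", "refine")) {
    for (nm in sample(names(m[[net]]), 4)) {
      p <- m[[net]][[nm]]
      i <- sample(length(p), 1)
      eps <- 1e-5
      m1 <- m; m1[[net]][[nm]][i] <- p[i] + eps
      m2 <- m; m2[[net]][[nm]][i] <- p[i] - eps
      fd <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
      an <- g[[net]][[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 5e-3)
    }
  }
})
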
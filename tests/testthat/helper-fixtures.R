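# Shared fixtures, built lazily and cached for the whole test run.
#
# All neural tests use the desk-scale configuration (8 feature channels,
# 8-8-8-8 UNet, SE reduction 4): same topology as the default config, small
# enough for CPU test budgets.

.fixture_cache <- new.env(parent = emptyenv())

# internal tensor-op aliases used by the network tests
ad_tape <- tmscodec:::ad_tape
ad_value <- tmscodec:::ad_value
ad_backward <- tmscodec:::ad_backward
ad_conv2d <- tmscodec:::ad_conv2d
ad_relu <- tmscodec:::ad_relu
ad_sigmoid <- tmscodec:::ad_sigmoid
ad_dense <- tmscodec:::ad_dense
ad_gap <- tmscodec:::ad_gap
ad_scale_channels <- tmscodec:::ad_scale_channels

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

test_config <- function() codec_config_small()

# A fixed random-initialization model.
random_model <- function() {
  fixture("random_model", function() codec_model(test_config(), seed = 101L))
}

# One toy-trained model shared across tests: 200 Adam steps on a mixed-regime
# synthetic training set.
toy_model <- function() {
  fixture("toy_model", function() {
    imgs <- generate_dataset(10, c("smooth", "texture", "speckle"),
                             seed = 42L, height = 48L, width = 48L)
    cfg <- train_config(crop_size = 32L, batch_size = 2L, lr = 1e-3,
                        epochs = 40L, seed = 5L)
    train_codec(random_model(), imgs, cfg)
  })
}

# Straight-line (loop-based) evaluation of the squeeze-and-excitation block:
# global average pool, two fully connected layers with ReLU/sigmoid, and
# channel-wise rescale. Independent of the package's tensor ops.
se_oracle <- function(x, w1, b1, w2, b2) {
  C <- dim(x)[3L]
  z <- numeric(C)
  for (ch in seq_len(C)) z[ch] <- mean(x[, , ch])
  hid <- pmax(as.vector(w1 %*% z) + b1, 0)
  s <- 1 / (1 + exp(-(as.vector(w2 %*% hid) + b2)))
  out <- x
  for (ch in seq_len(C)) out[, , ch] <- x[, , ch] * s[ch]
  out
}

# Brute-force double-sum cross-entropy of one-hot targets (natural log).
ppl_oracle <- function(residual, prob, weight) {
  total <- 0; n <- 0
  for (i in seq_len(nrow(residual))) for (j in seq_len(ncol(residual))) {
    if (weight[i, j] > 0) {
      total <- total - log(prob[i, j, residual[i, j] + 1L])
      n <- n + 1
    }
  }
  total / n
}

random_plane <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

expect_plane_equal <- function(a, b) {
  expect_equal(unname(a), unname(b), tolerance = 0)
}
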
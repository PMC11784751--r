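test_that("probability quantization yields exact 2^16 totals with min count 1", {
  onehot <- c(1, rep(0, 510))
  f <- quantize_probabilities(onehot)
  expect_equal(sum(f), 65536)
  expect_equal(f[1], 65536 - 510)
  expect_true(all(f[-1] == 1))

  # uniform: floor((2^16-511)/511)+1 = 128 per class; the rounding surplus
  # of 128 lands on the lowest-index maximal class
  unif <- rep(1 / 511, 511)
  fu <- quantize_probabilities(unif)
  expect_equal(sum(fu), 65536)
  expect_equal(fu[1], 256)
  expect_true(all(fu[-1] == 128))

  set.seed(4)
  p <- matrix(rexp(20 * 511)^2, 20, 511)
  p <- p / rowSums(p)
  fm <- quantize_probabilities(p)
  expect_true(all(rowSums(fm) == 65536))
  expect_true(all(fm >= 1))
  # per-class quantization distortion bound
  expect_true(all(abs(fm / 65536 - p) <= (511 + 1) / 65536))
  # stability: re-quantizing the normalized table yields another valid table
  # within the same distortion bound (elementwise idempotence does not hold:
  # the scale factor 2^16-511 shifts every count above ~128 and the surplus
  # rule moves the difference to the largest class)
  f2 <- quantize_probabilities(fm[3, ] / 65536)
  expect_equal(sum(f2), 65536)
  expect_true(all(abs(f2 - fm[3, ]) / 65536 <= (511 + 1) / 65536))

  expect_error(quantize_probabilities(c(-1, rep(0.5, 510))), "nonnegative")
  expect_error(quantize_probabilities(rep(1, 511)), "sum to 1")
})

test_that("arithmetic coder round-trips arbitrary streams exactly", {
  expect_lte(length(ac_encode(integer(0), matrix(numeric(0), 0, 511))), 8)
  expect_identical(ac_decode(raw(0), matrix(numeric(0), 0, 511), 0L), integer(0))

  set.seed(11)
  for (trial in 1:8) {
    n <- sample(c(1, 3, 50, 400), 1)
    p <- matrix(rexp(n * 511)^sample(1:3, 1), n, 511)
    p <- p / rowSums(p)
    tb <- quantize_probabilities(p)
    syms <- vapply(seq_len(n), function(i) sample(0:510, 1, prob = tb[i, ]),
                   integer(1))
    pay <- ac_encode(syms, tb)
    expect_identical(ac_decode(pay, tb, n), syms)
  }
})

test_that("coded length stays within the Shannon bound of the quantized model", {
  set.seed(12)
  n <- 2000
  p <- matrix(rexp(n * 511)^2, n, 511)
  p <- p / rowSums(p)
  tb <- quantize_probabilities(p)
  syms <- vapply(seq_len(n), function(i) sample(0:510, 1, prob = tb[i, ]),
                 integer(1))
  pay <- ac_encode(syms, tb)
  expect_lte(8 * length(pay),
             tmscodec:::stream_shannon_bits(syms, tb) + 64)
})

test_that("probability-1 symbols cost nothing beyond termination", {
  n <- 500
  tb <- quantize_probabilities(c(1, rep(0, 510)))
  pay <- ac_encode(rep(0L, n), matrix(tb, n, 511, byrow = TRUE))
  # the forced symbol has probability (2^16-510)/2^16, so the whole stream
  # needs only a few bits plus the fixed terminator
  expect_lte(length(pay), 8)
  expect_identical(ac_decode(pay, matrix(tb, n, 511, byrow = TRUE), n),
                   rep(0L, n))
})

test_that("shannon_bits computes -log2(p)", {
  expect_equal(shannon_bits(0.5), 1.0)
  expect_equal(shannon_bits(1.0), 0.0)
  expect_equal(shannon_bits(0.25), 2.0)
  expect_error(shannon_bits(0), "positive")
})
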
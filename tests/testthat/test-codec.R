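test_that("anchor codec round-trips planes losslessly and compresses", {
  for (seed in 1:5) {
    a <- random_plane(13, 17, seed)
    enc <- encode_anchor(a, "png")
    expect_equal(enc$codec_id, 0L)
    expect_plane_equal(decode_anchor(enc$payload, enc$codec_id), a)
  }
  cst <- matrix(42, 32, 32)
  enc <- encode_anchor(cst, "png")
  expect_lt(length(enc$payload), 32 * 32)
})

test_that("container serialization is byte-exact and rejects corruption", {
  set.seed(5)
  for (trial in 1:10) {
    plan_vals <- sample(c("fast", "slow"), 3, replace = TRUE)
    plan <- route_plan(plan_vals[1], plan_vals[2], plan_vals[3])
    n_chunks <- 1L + sum(ifelse(plan == "slow", 2L, 1L))
    cont <- list(original_height = sample.int(4000L, 1),
                 original_width = sample.int(4000L, 1),
                 anchor_codec_id = 0L,
                 route_bits = tmscodec:::route_bits_encode(plan),
                 chunks = lapply(seq_len(n_chunks), function(i)
                   as.raw(sample(0:255, sample(0:40, 1), replace = TRUE))))
    bytes <- write_container(cont)
    back <- read_container(bytes)
    expect_identical(back$original_height, cont$original_height)
    expect_identical(back$original_width, cont$original_width)
    expect_identical(back$chunks, cont$chunks)
    expect_identical(write_container(back), bytes)
    # truncation and bad magic are detected
    expect_error(read_container(bytes[1:10]), "truncated")
    bad <- bytes; bad[1] <- as.raw(88)
    expect_error(read_container(bad), "magic")
  }
})

test_that("a container missing one chunk is rejected", {
  m <- random_model()
  img <- generate_image("smooth", 20, 20, seed = 3)
  bytes <- compress(img, m, route_plan("fast"))
  cont <- read_container(bytes)
  cont$chunks <- cont$chunks[-4]
  expect_error(read_container(write_container(cont)), "chunk count")
})

test_that("route plans map to the documented chunk counts and header bits", {
  m <- random_model()
  img <- generate_image("texture", 24, 24, seed = 8)
  fast <- read_container(compress(img, m, route_plan("fast")))
  expect_length(fast$chunks, 4L)
  slow <- read_container(compress(img, m, route_plan("slow")))
  expect_length(slow$chunks, 7L)
  mixed <- read_container(compress(img, m, route_plan("slow", "fast", "slow")))
  expect_length(mixed$chunks, 6L)
  expect_identical(
    unname(unclass(tmscodec:::route_bits_decode(mixed$route_bits))),
    c("slow", "fast", "slow"))
})

test_that("compression is deterministic: identical containers across runs", {
  m <- random_model()
  img <- generate_image("speckle", 28, 28, seed = 9)
  c1 <- compress(img, m, route_plan("slow"))
  c2 <- compress(img, m, route_plan("slow"))
  expect_identical(c1, c2)
})

test_that("fast and slow routes decode to the same image", {
  m <- toy_model()
  img <- generate_image("mixed", 30, 26, seed = 12)
  for (plan in list(route_plan("fast"), route_plan("slow"),
                    route_plan("fast", "slow", "fast"))) {
    expect_plane_equal(decompress(compress(img, m, plan), m), img)
  }
})

test_that("odd-sized images restore their original dimensions", {
  m <- random_model()
  for (dims in list(c(21L, 33L), c(16L, 27L), c(19L, 16L))) {
    img <- generate_image("texture", dims[1], dims[2], seed = sum(dims))
    out <- decompress(compress(img, m, route_plan("slow", "fast", "fast")), m)
    expect_identical(dim(out), dims)
    expect_plane_equal(out, img)
  }
})

test_that("container_info reports sizes consistent with the byte stream", {
  m <- random_model()
  img <- generate_image("smooth", 20, 24, seed = 2)
  bytes <- compress(img, m, route_plan("fast"))
  info <- container_info(bytes)
  expect_equal(info$total_bytes, length(bytes))
  expect_equal(info$bpp, 8 * length(bytes) / (20 * 24))
  expect_equal(sum(info$chunk_bytes) + 16 + 4 * length(info$chunk_bytes),
               length(bytes))
})
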
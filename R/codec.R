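# Compression pipeline and container format.
#
# compress(): pad to even dims, split into level-1 planes a/b/c/d, code the
# anchor plane a with a conventional codec (PNG, or JPEG-XL when cjxl/djxl
# are on PATH), then code d, b, c in that order. Each position takes either
# the fast route (one plane-network pass, whole-plane residual in one chunk)
# or the slow route (stage 1: plane-network outputs column-masked to the even
# columns; stage 2: refine network conditioned on the now-known even columns,
# masked to the odd columns; two chunks). The decoder mirrors this exactly,
# re-running each network on the already-decoded priors, which is why the
# whole scheme hinges on bit-reproducible forward passes.
#
# Container layout (all integers big-endian):
#   magic "LCTM" | version u8 | original_height u32 | original_width u32 |
#   bit_depth u8 (=8) | anchor_codec_id u8 (0=PNG, 1=JPEG-XL) |
#   route_bits u8 (bit0=d, bit1=b, bit2=c; 1=slow) |
#   then chunks: u32 length + payload each.
# Chunk count: 1 (anchor) + per position 1 if fast else 2.

CONTAINER_MAGIC <- charToRaw("LCTM")
CONTAINER_VERSION <- 1L   # v1 = polyphase level-1 split, chunk-per-stage AC

u32_to_raw <- function(x) {
  stopifnot(x >= 0, x < 2^32)
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

raw_to_u32 <- function(r) {
  v <- as.integer(r)
  ((v[1L] * 256 + v[2L]) * 256 + v[3L]) * 256 + v[4L]
}

#' Construct a route plan
#'
#' One route per coded position (in coding order d, b, c): `"fast"` codes the
#' whole plane in one network pass; `"slow"` codes the even columns first and
#' then refines the odd columns with the second network.
#'
#' @param d,b,c `"fast"` or `"slow"`; a single unnamed value recycles to all
#'   three positions.
#' @return Named character vector of class `route_plan`.
#' @export
route_plan <- function(d = "fast", b = d, c = d) {
  plan <- c(d = match.arg(d, c("fast", "slow")),
            b = match.arg(b, c("fast", "slow")),
            c = match.arg(c, c("fast", "slow")))
  structure(plan, class = "route_plan")
}

route_bits_encode <- function(plan) {
  sum(2^(0:2) * (plan == "slow"))
}

route_bits_decode <- function(bits) {
  structure(ifelse(bitwAnd(bits, 2^(0:2)) > 0, "slow", "fast"),
            names = c("d", "b", "c"), class = "route_plan")
}

# ---- anchor codec -----------------------------------------------------------

jxl_available <- function() {
  nzchar(Sys.which("cjxl")) && nzchar(Sys.which("djxl"))
}

#' Losslessly code the anchor plane with a conventional codec
#'
#' @param a Pixel matrix in `[0, 255]`.
#' @param codec `"png"` (default) or `"jxl"`; JPEG-XL requires the cjxl/djxl
#'   binaries and falls back to PNG (with a warning) when they are absent.
#' @return List with `payload` (raw) and `codec_id` (0 = PNG, 1 = JPEG-XL).
#' @export
encode_anchor <- function(a, codec = c("png", "jxl")) {
  codec <- match.arg(codec)
  if (codec == "jxl" && !jxl_available()) {
    warning("JPEG-XL binaries not found; falling back to PNG anchor")
    codec <- "png"
  }
  if (codec == "png") {
    list(payload = png::writePNG(a / 255, raw()), codec_id = 0L)
  } else {
    src <- tempfile(fileext = ".png"); dst <- tempfile(fileext = ".jxl")
    on.exit(unlink(c(src, dst)), add = TRUE)
    png::writePNG(a / 255, src)
    status <- system2("cjxl", c("-d", "0", shQuote(src), shQuote(dst)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("cjxl failed")
    list(payload = readBin(dst, "raw", file.size(dst)), codec_id = 1L)
  }
}

#' @rdname encode_anchor
#' @param payload Raw vector from [encode_anchor()].
#' @param codec_id Codec id from the container header.
#' @export
decode_anchor <- function(payload, codec_id) {
  if (codec_id == 0L) {
    img <- png::readPNG(payload)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    round(img * 255)
  } else if (codec_id == 1L) {
    if (!jxl_available()) stop("container uses JPEG-XL but djxl is not on PATH")
    src <- tempfile(fileext = ".jxl"); dst <- tempfile(fileext = ".png")
    on.exit(unlink(c(src, dst)), add = TRUE)
    writeBin(payload, src)
    status <- system2("djxl", c(shQuote(src), shQuote(dst)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("djxl failed")
    img <- png::readPNG(dst)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    round(img * 255)
  } else stop("unknown anchor codec id: ", codec_id)
}

# ---- container I/O ----------------------------------------------------------

#' Serialize / parse the compressed container
#'
#' @param container List with fields `original_height`, `original_width`,
#'   `anchor_codec_id`, `route_bits`, `chunks` (list of raw vectors).
#' @return `write_container` a raw vector; `read_container` the container list.
#' @export
write_container <- function(container) {
  header <- c(CONTAINER_MAGIC, as.raw(CONTAINER_VERSION),
              u32_to_raw(container$original_height),
              u32_to_raw(container$original_width),
              as.raw(8L), as.raw(container$anchor_codec_id),
              as.raw(container$route_bits))
  body <- lapply(container$chunks, function(ch) c(u32_to_raw(length(ch)), ch))
  c(header, do.call(c, body))
}

#' @rdname write_container
#' @param bytes Raw vector.
#' @export
read_container <- function(bytes) {
  if (length(bytes) < 16L) stop("truncated container")
  if (!identical(bytes[1:4], CONTAINER_MAGIC)) stop("bad magic: not a LCTM container")
  version <- as.integer(bytes[5L])
  if (version != CONTAINER_VERSION) stop("unsupported container version: ", version)
  oh <- as.integer(raw_to_u32(bytes[6:9])); ow <- as.integer(raw_to_u32(bytes[10:13]))
  depth <- as.integer(bytes[14L])
  if (depth != 8L) stop("unsupported bit depth: ", depth)
  codec_id <- as.integer(bytes[15L])
  route_bits <- as.integer(bytes[16L])
  chunks <- list()
  pos <- 17L
  while (pos <= length(bytes)) {
    if (pos + 3L > length(bytes)) stop("truncated chunk header")
    len <- raw_to_u32(bytes[pos:(pos + 3L)])
    pos <- pos + 4L
    if (pos + len - 1L > length(bytes)) stop("truncated chunk payload")
    chunks[[length(chunks) + 1L]] <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0L)
    pos <- pos + len
  }
  plan <- route_bits_decode(route_bits)
  expected <- 1L + sum(ifelse(plan == "slow", 2L, 1L))
  if (length(chunks) != expected)
    stop(sprintf("chunk count mismatch: found %d, header implies %d",
                 length(chunks), expected))
  list(original_height = oh, original_width = ow, bit_depth = 8L,
       anchor_codec_id = codec_id, route_bits = route_bits, chunks = chunks)
}

# ---- plane-level coding helpers ---------------------------------------------

# Row-major symbol order over an h x w plane (row index slow, column fast).
rowmajor_index <- function(h, w) as.vector(t(matrix(seq_len(h * w), h, w)))

plane_to_symbols <- function(plane) {
  as.integer(plane)[rowmajor_index(nrow(plane), ncol(plane))]
}

symbols_to_plane <- function(symbols, h, w) {
  m <- matrix(0L, h, w)
  m[rowmajor_index(h, w)] <- symbols
  m
}

prob_to_tables <- function(prob) {
  d <- dim(prob)
  m <- matrix(prob, d[1L] * d[2L], d[3L])[rowmajor_index(d[1L], d[2L]), , drop = FALSE]
  quantize_probabilities(m)
}

encode_plane_chunk <- function(residual, prob) {
  ac_encode(plane_to_symbols(residual), prob_to_tables(prob))
}

decode_plane_chunk <- function(payload, prob) {
  d <- dim(prob)
  syms <- ac_decode(payload, prob_to_tables(prob), d[1L] * d[2L])
  symbols_to_plane(syms, d[1L], d[2L])
}

left_masked <- function(plane) {
  plane[, !col_parity_kept(ncol(plane), "even")] <- 0
  plane
}

# Refine-network context: the plane's even columns with each odd column
# filled by the average of its two even neighbors (left only at the right
# border). A pure function of the even columns, so the decoder reproduces it
# exactly, and it hands the network its best simple predictor up front.
left_context <- function(plane) {
  W <- ncol(plane)
  odd <- which(!col_parity_kept(W, "even"))
  for (j in odd) {
    plane[, j] <- if (j + 1L <= W) (plane[, j - 1L] + plane[, j + 1L]) / 2
                  else plane[, j - 1L]
  }
  plane
}

# ---- compress / decompress --------------------------------------------------

#' Compress an image losslessly
#'
#' @param image Integer-valued matrix in `[0, 255]`, any size `>= 2 x 2`.
#' @param model A [codec_model()] (the decoder must use the identical model).
#' @param plan A [route_plan()].
#' @param anchor `"png"` or `"jxl"` anchor codec for subimage a.
#' @param verbose Print per-chunk bit counts.
#' @return Raw vector: the self-describing container.
#' @export
compress <- function(image, model, plan = route_plan("fast"), anchor = "png",
                     verbose = FALSE) {
  stopifnot(inherits(model, "codec_model"), inherits(plan, "route_plan"))
  image <- check_plane(image)
  oh <- nrow(image); ow <- ncol(image)
  padded <- pad_to_even(image)
  parts <- split_level1(padded)
  anc <- encode_anchor(parts$a, anchor)
  chunks <- list(anc$payload)
  if (verbose) message(sprintf("anchor: %d bytes", length(anc$payload)))
  priors <- list(parts$a)
  for (pos in c("d", "b", "c")) {
    true <- parts[[pos]]
    out <- forward_plane(model, priors)
    if (plan[[pos]] == "fast") {
      res <- compute_residual(true, out$pred)
      chunks[[length(chunks) + 1L]] <- encode_plane_chunk(res, out$prob)
      if (verbose) message(sprintf("%s fast: %d bytes", pos,
                                   length(chunks[[length(chunks)]])))
    } else {
      res1 <- mask_residual(compute_residual(true, out$pred), keep = "even")
      prob1 <- mask_probability(out$prob, keep = "even")
      chunks[[length(chunks) + 1L]] <- encode_plane_chunk(res1, prob1)
      out2 <- forward_refine(model, priors, left_context(true))
      res2 <- mask_residual(compute_residual(true, out2$pred), keep = "odd")
      prob2 <- mask_probability(out2$prob, keep = "odd")
      chunks[[length(chunks) + 1L]] <- encode_plane_chunk(res2, prob2)
      if (verbose) message(sprintf("%s slow: %d + %d bytes", pos,
                                   length(chunks[[length(chunks) - 1L]]),
                                   length(chunks[[length(chunks)]])))
    }
    priors <- c(priors, list(true))
  }
  write_container(list(original_height = oh, original_width = ow,
                       anchor_codec_id = anc$codec_id,
                       route_bits = route_bits_encode(plan), chunks = chunks))
}

#' Decompress a container back to the original image
#'
#' @param bytes Raw container from [compress()].
#' @param model The identical `codec_model` used to compress.
#' @return The original pixel matrix, bit-exact.
#' @export
decompress <- function(bytes, model) {
  stopifnot(inherits(model, "codec_model"))
  cont <- read_container(bytes)
  plan <- route_bits_decode(cont$route_bits)
  a <- decode_anchor(cont$chunks[[1L]], cont$anchor_codec_id)
  priors <- list(a)
  parts <- list(a = a)
  ci <- 2L
  for (pos in c("d", "b", "c")) {
    out <- forward_plane(model, priors)
    if (plan[[pos]] == "fast") {
      res <- decode_plane_chunk(cont$chunks[[ci]], out$prob); ci <- ci + 1L
      plane <- reconstruct_pixels(res, out$pred)
    } else {
      prob1 <- mask_probability(out$prob, keep = "even")
      res1 <- decode_plane_chunk(cont$chunks[[ci]], prob1); ci <- ci + 1L
      full1 <- reconstruct_pixels_masked(res1, out$pred, keep = "even")
      out2 <- forward_refine(model, priors, left_context(full1))
      prob2 <- mask_probability(out2$prob, keep = "odd")
      res2 <- decode_plane_chunk(cont$chunks[[ci]], prob2); ci <- ci + 1L
      full2 <- reconstruct_pixels_masked(res2, out2$pred, keep = "odd")
      kept <- col_parity_kept(ncol(full1), "even")
      plane <- full1
      plane[, !kept] <- full2[, !kept]
    }
    parts[[pos]] <- plane
    priors <- c(priors, list(plane))
  }
  padded <- merge_level1(parts)
  padded[seq_len(cont$original_height), seq_len(cont$original_width), drop = FALSE]
}

# Reconstruct only the kept-parity columns; others are left at 0 (their
# residual symbols carry no information by construction).
reconstruct_pixels_masked <- function(residual, pred, keep) {
  kept <- col_parity_kept(ncol(residual), keep)
  out <- matrix(0, nrow(residual), ncol(residual))
  out[, kept] <- reconstruct_pixels(residual[, kept, drop = FALSE],
                                    pred[, kept, drop = FALSE])
  out
}

#' Summarize a container without decoding it
#'
#' @param bytes Raw container.
#' @return List with dimensions, routes, anchor codec, per-chunk byte counts
#'   and overall bits per pixel.
#' @export
container_info <- function(bytes) {
  cont <- read_container(bytes)
  plan <- route_bits_decode(cont$route_bits)
  list(
    height = cont$original_height,
    width = cont$original_width,
    anchor = c("png", "jxl")[cont$anchor_codec_id + 1L],
    routes = plan,
    chunk_bytes = vapply(cont$chunks, length, numeric(1L)),
    total_bytes = length(bytes),
    bpp = 8 * length(bytes) / (cont$original_height * cont$original_width)
  )
}
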
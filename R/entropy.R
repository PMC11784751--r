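# Static-model arithmetic coding of residual symbols.
#
# Per-pixel 511-class probabilities are quantized to integer frequency
# tables with total 2^16 and a minimum count of 1 per class, which makes the
# coder deterministic across platforms and guarantees any symbol remains
# decodable even when the model thinks it impossible. The coder itself is a
# 32-bit integer arithmetic coder (Witten-Neal-Cleary style) with underflow
# counting, implemented on doubles (exact to 2^53, so 32-bit state times
# 16-bit totals never loses precision).

AC_TOTAL <- 65536          # 2^16, the fixed frequency-table total
AC_CLASSES <- 511L

#' Quantize a probability vector to an integer frequency table
#'
#' Each class gets `floor(p * (2^16 - 511)) + 1` counts (so at least 1), and
#' the rounding surplus or deficit against 2^16 is absorbed by the
#' largest-frequency class (lowest index on ties).
#'
#' @param p Numeric vector of 511 nonnegative values summing to 1 (within
#'   `1e-5`), or a matrix with one 511-vector per row for many pixels.
#' @return Integer-valued vector (or matrix) of frequencies with row total
#'   exactly 2^16.
#' @export
quantize_probabilities <- function(p) {
  if (is.matrix(p)) return(quantize_prob_matrix(p))
  quantize_prob_matrix(matrix(p, 1L))[1L, ]
}

quantize_prob_matrix <- function(p) {
  stopifnot(ncol(p) == AC_CLASSES)
  if (anyNA(p) || any(p < 0)) stop("probabilities must be finite and nonnegative")
  s <- rowSums(p)
  if (any(abs(s - 1) > 1e-5)) stop("probabilities must sum to 1 within 1e-5")
  f <- floor(p * (AC_TOTAL - AC_CLASSES)) + 1
  diffs <- AC_TOTAL - rowSums(f)
  jmax <- max.col(f, ties.method = "first")
  idx <- cbind(seq_len(nrow(f)), jmax)
  f[idx] <- f[idx] + diffs
  if (any(f < 1)) stop("frequency quantization underflow")
  f
}

#' Shannon information content of a probability
#'
#' @param p Probability in `(0, 1]`.
#' @return `-log2(p)`, the optimal code length in bits.
#' @examples
#' shannon_bits(0.5)
#' @export
shannon_bits <- function(p) {
  if (any(p <= 0)) stop("p must be positive")
  -log2(p)
}

# ---- bit buffer -------------------------------------------------------------

new_bitbuf <- function() {
  e <- new.env(parent = emptyenv())
  e$bits <- integer(4096L)
  e$n <- 0L
  e
}

buf_push <- function(buf, bit, pending = 0L) {
  need <- buf$n + 1L + pending
  while (need > length(buf$bits)) buf$bits <- c(buf$bits, integer(length(buf$bits)))
  buf$bits[buf$n + 1L] <- bit
  if (pending > 0L) buf$bits[buf$n + 1L + seq_len(pending)] <- 1L - bit
  buf$n <- need
}

bits_to_raw <- function(bits) {
  pad <- (-length(bits)) %% 8L
  packBits(as.integer(c(bits, integer(pad))), type = "raw")
}

raw_to_bits <- function(bytes) as.integer(rawToBits(bytes))

# ---- coder ------------------------------------------------------------------

AC_FULL <- 2^32
AC_HALF <- 2^31
AC_QUART <- 2^30

# Row-wise exclusive/inclusive cumulative bounds of symbol s (1-based) in
# frequency row f.
freq_bounds <- function(f, s) {
  cs <- cumsum(f)
  lo <- if (s == 1L) 0 else cs[s - 1L]
  c(lo, cs[s])
}

#' Arithmetic-code a symbol stream under per-symbol frequency tables
#'
#' @param symbols Integer vector, each in `[0, 510]`.
#' @param tables Matrix with one frequency-table row (total 2^16) per symbol,
#'   or a single vector applied to all symbols.
#' @return Raw vector payload; [ac_decode()] inverts it exactly.
#' @export
ac_encode <- function(symbols, tables) {
  n <- length(symbols)
  if (is.null(dim(tables))) tables <- matrix(tables, n, length(tables), byrow = TRUE)
  stopifnot(nrow(tables) == n || n == 0L)
  low <- 0; high <- AC_FULL - 1; pending <- 0L
  buf <- new_bitbuf()
  for (i in seq_len(n)) {
    s <- symbols[i] + 1L
    b <- freq_bounds(tables[i, ], s)
    span <- high - low + 1
    high <- low + floor(span * b[2L] / AC_TOTAL) - 1
    low <- low + floor(span * b[1L] / AC_TOTAL)
    repeat {
      if (high < AC_HALF) {
        buf_push(buf, 0L, pending); pending <- 0L
      } else if (low >= AC_HALF) {
        buf_push(buf, 1L, pending); pending <- 0L
        low <- low - AC_HALF; high <- high - AC_HALF
      } else if (low >= AC_QUART && high < 3 * AC_QUART) {
        pending <- pending + 1L
        low <- low - AC_QUART; high <- high - AC_QUART
      } else break
      low <- 2 * low; high <- 2 * high + 1
    }
  }
  # flush: emit enough bits to pin the final interval
  pending <- pending + 1L
  buf_push(buf, if (low < AC_QUART) 0L else 1L, pending)
  bits_to_raw(buf$bits[seq_len(buf$n)])
}

#' Decode an arithmetic-coded symbol stream
#'
#' @param payload Raw vector from [ac_encode()].
#' @param tables The identical frequency tables the encoder used.
#' @param n Number of symbols to decode.
#' @return Integer vector of `n` symbols in `[0, 510]`.
#' @export
ac_decode <- function(payload, tables, n) {
  if (n == 0L) return(integer(0L))
  if (is.null(dim(tables))) tables <- matrix(tables, n, length(tables), byrow = TRUE)
  stopifnot(nrow(tables) == n)
  bits <- raw_to_bits(payload)
  nb <- length(bits)
  getbit <- function(k) if (k <= nb) bits[k] else 0L
  pos <- 0L
  value <- 0
  for (j in 1:32) { pos <- pos + 1L; value <- 2 * value + getbit(pos) }
  low <- 0; high <- AC_FULL - 1
  out <- integer(n)
  for (i in seq_len(n)) {
    f <- tables[i, ]
    cs <- cumsum(f)
    span <- high - low + 1
    target <- floor(((value - low + 1) * AC_TOTAL - 1) / span)
    s <- findInterval(target, cs) + 1L
    if (s > length(f)) stop("truncated or corrupted payload")
    lo <- if (s == 1L) 0 else cs[s - 1L]
    out[i] <- s - 1L
    high <- low + floor(span * cs[s] / AC_TOTAL) - 1
    low <- low + floor(span * lo / AC_TOTAL)
    repeat {
      if (high < AC_HALF) {
      } else if (low >= AC_HALF) {
        low <- low - AC_HALF; high <- high - AC_HALF; value <- value - AC_HALF
      } else if (low >= AC_QUART && high < 3 * AC_QUART) {
        low <- low - AC_QUART; high <- high - AC_QUART; value <- value - AC_QUART
      } else break
      low <- 2 * low; high <- 2 * high + 1
      pos <- pos + 1L; value <- 2 * value + getbit(pos)
    }
  }
  out
}

# Ideal code length in bits of a stream under quantized tables.
stream_shannon_bits <- function(symbols, tables) {
  if (length(symbols) == 0L) return(0)
  if (is.null(dim(tables)))
    tables <- matrix(tables, length(symbols), length(tables), byrow = TRUE)
  q <- tables[cbind(seq_along(symbols), symbols + 1L)] / AC_TOTAL
  sum(-log2(q))
}
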
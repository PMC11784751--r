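# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every tensor op below takes a `tape` as its first argument. With
# `tape = NULL` the op computes and returns a plain array (inference path);
# with a live tape it returns a node recorded for the backward sweep, so the
# encoder/decoder forward code and the training code share one implementation.
# Spatial tensors are arrays with dim c(H, W, C); parameter gradients
# accumulate on leaf nodes.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_is_node <- function(x) is.environment(x)

ad_value <- function(x) if (ad_is_node(x)) x$value else x

ad_leaf <- function(tape, value) {
  ad_record(tape, value, NULL)
}

ad_record <- function(tape, value, backward) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$backward <- backward
  if (!is.null(tape)) {
    if (tape$n >= length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- n
  }
  n
}

ad_accum <- function(node, g) {
  if (!ad_is_node(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Run the backward sweep from a scalar loss node.
ad_backward <- function(tape, loss) {
  stopifnot(ad_is_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  if (tape$n > 0L) {
    for (i in seq.int(tape$n, 1L)) {
      nd <- tape$nodes[[i]]
      if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
    }
  }
  invisible(NULL)
}

ad_op <- function(tape, value, backward) {
  if (is.null(tape)) return(value)
  ad_record(tape, value, backward)
}

as_hwc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

# ---- convolution ------------------------------------------------------------

# im2col for odd square kernels with zero "same" padding; column order is
# (dy fastest, then dx, then input channel), matching matrix(w, kh*kw*Cin, Cout)
# on weight arrays of dim c(kh, kw, Cin, Cout).
im2col <- function(x, kh, kw) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + kh - 1L, W + kw - 1L, C))
  xp[ph + seq_len(H), pw + seq_len(W), ] <- x
  cols <- matrix(0, H * W, kh * kw * C)
  k <- 0L
  for (c in seq_len(C)) for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    k <- k + 1L
    cols[, k] <- xp[dy + 0:(H - 1L), dx + 0:(W - 1L), c]
  }
  cols
}

col2im <- function(dcols, H, W, C, kh, kw) {
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  dxp <- array(0, c(H + kh - 1L, W + kw - 1L, C))
  k <- 0L
  for (c in seq_len(C)) for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    k <- k + 1L
    dxp[dy + 0:(H - 1L), dx + 0:(W - 1L), c] <-
      dxp[dy + 0:(H - 1L), dx + 0:(W - 1L), c] + matrix(dcols[, k], H, W)
  }
  array(dxp[ph + seq_len(H), pw + seq_len(W), , drop = FALSE], c(H, W, C))
}

# 2-D convolution, stride 1, zero same-padding. w: c(kh, kw, Cin, Cout), b: Cout.
ad_conv2d <- function(tape, x, w, b) {
  xv <- as_hwc(ad_value(x)); wv <- ad_value(w); bv <- ad_value(b)
  dw <- dim(wv); kh <- dw[1L]; kw <- dw[2L]; Cin <- dw[3L]; Cout <- dw[4L]
  d <- dim(xv); H <- d[1L]; W <- d[2L]
  stopifnot(d[3L] == Cin)
  wmat <- matrix(wv, kh * kw * Cin, Cout)
  if (kh == 1L && kw == 1L) {
    cols <- matrix(xv, H * W, Cin)
  } else {
    cols <- im2col(xv, kh, kw)
  }
  outm <- cols %*% wmat
  outm <- sweep(outm, 2L, bv, "+")
  out <- array(outm, c(H, W, Cout))
  ad_op(tape, out, function(g) {
    gm <- matrix(g, H * W, Cout)
    ad_accum(w, array(crossprod(cols, gm), dim(wv)))
    ad_accum(b, colSums(gm))
    if (ad_is_node(x)) {
      dcols <- gm %*% t(wmat)
      dx <- if (kh == 1L && kw == 1L) array(dcols, c(H, W, Cin))
            else col2im(dcols, H, W, Cin, kh, kw)
      if (is.matrix(ad_value(x))) dim(dx) <- dim(ad_value(x))
      ad_accum(x, dx)
    }
  })
}

# ---- pointwise --------------------------------------------------------------

ad_relu <- function(tape, x) {
  xv <- ad_value(x)
  out <- pmax(xv, 0)
  ad_op(tape, out, function(g) ad_accum(x, g * (xv > 0)))
}

ad_sigmoid <- function(tape, x) {
  out <- 1 / (1 + exp(-ad_value(x)))
  ad_op(tape, out, function(g) ad_accum(x, g * out * (1 - out)))
}

ad_add <- function(tape, a, b) {
  out <- ad_value(a) + ad_value(b)
  ad_op(tape, out, function(g) { ad_accum(a, g); ad_accum(b, g) })
}

ad_scale <- function(tape, x, k) {
  out <- ad_value(x) * k
  ad_op(tape, out, function(g) ad_accum(x, g * k))
}

# ---- dense / squeeze-excitation pieces --------------------------------------

# w: c(out, in), z: length-in vector.
ad_dense <- function(tape, z, w, b) {
  zv <- ad_value(z); wv <- ad_value(w); bv <- ad_value(b)
  out <- as.vector(wv %*% zv) + bv
  ad_op(tape, out, function(g) {
    ad_accum(w, outer(g, zv))
    ad_accum(b, g)
    if (ad_is_node(z)) ad_accum(z, as.vector(crossprod(wv, g)))
  })
}

# Global average pool over H, W: returns length-C vector.
ad_gap <- function(tape, x) {
  xv <- as_hwc(ad_value(x))
  d <- dim(xv); n <- d[1L] * d[2L]
  out <- colSums(matrix(xv, n, d[3L])) / n
  ad_op(tape, out, function(g) {
    dx <- array(rep(g / n, each = n), d)
    ad_accum(x, dx)
  })
}

# Multiply each channel of x by scalar s[c] (the SE rescale).
ad_scale_channels <- function(tape, x, s) {
  xv <- as_hwc(ad_value(x)); sv <- ad_value(s)
  d <- dim(xv)
  out <- sweep(xv, 3L, sv, "*")
  ad_op(tape, out, function(g) {
    ad_accum(x, sweep(g, 3L, sv, "*"))
    ad_accum(s, colSums(matrix(g * xv, d[1L] * d[2L], d[3L])))
  })
}

# ---- resolution changes -----------------------------------------------------

ad_avgpool2 <- function(tape, x) {
  xv <- as_hwc(ad_value(x))
  d <- dim(xv); H <- d[1L]; W <- d[2L]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  out <- (xv[io, jo, , drop = FALSE] + xv[io + 1L, jo, , drop = FALSE] +
          xv[io, jo + 1L, , drop = FALSE] + xv[io + 1L, jo + 1L, , drop = FALSE]) / 4
  ad_op(tape, out, function(g) {
    dx <- array(0, d)
    g4 <- g / 4
    dx[io, jo, ] <- g4; dx[io + 1L, jo, ] <- g4
    dx[io, jo + 1L, ] <- g4; dx[io + 1L, jo + 1L, ] <- g4
    ad_accum(x, dx)
  })
}

ad_upsample2 <- function(tape, x) {
  xv <- as_hwc(ad_value(x))
  d <- dim(xv); H <- d[1L]; W <- d[2L]
  ri <- rep(seq_len(H), each = 2L); cj <- rep(seq_len(W), each = 2L)
  out <- xv[ri, cj, , drop = FALSE]
  ad_op(tape, out, function(g) {
    io <- seq(1L, 2L * H, 2L); jo <- seq(1L, 2L * W, 2L)
    dx <- g[io, jo, , drop = FALSE] + g[io + 1L, jo, , drop = FALSE] +
      g[io, jo + 1L, , drop = FALSE] + g[io + 1L, jo + 1L, , drop = FALSE]
    ad_accum(x, dx)
  })
}

ad_concat <- function(tape, a, b) {
  av <- as_hwc(ad_value(a)); bv <- as_hwc(ad_value(b))
  da <- dim(av); db <- dim(bv)
  stopifnot(da[1L] == db[1L], da[2L] == db[2L])
  out <- array(c(av, bv), c(da[1L], da[2L], da[3L] + db[3L]))
  ad_op(tape, out, function(g) {
    ad_accum(a, g[, , seq_len(da[3L]), drop = FALSE])
    ad_accum(b, g[, , da[3L] + seq_len(db[3L]), drop = FALSE])
  })
}

# Mirror-extend indices 1..n to length m (period 2n-2; degenerates to
# replication at n = 1). Used to pad planes to UNet-divisible sizes.
reflect_idx <- function(n, m) {
  if (n == 1L) return(rep(1L, m))
  period <- 2L * n - 2L
  k <- (seq_len(m) - 1L) %% period
  ifelse(k < n, k + 1L, period - k + 1L)
}

# Pad spatially to (H2, W2) by mirror extension; crop is its exact left inverse.
ad_pad_reflect <- function(tape, x, H2, W2) {
  xv <- as_hwc(ad_value(x))
  d <- dim(xv)
  ri <- reflect_idx(d[1L], H2); cj <- reflect_idx(d[2L], W2)
  out <- xv[ri, cj, , drop = FALSE]
  ad_op(tape, out, function(g) {
    gm <- rowsum(matrix(g, H2, W2 * d[3L]), ri)
    dx <- array(0, c(d[1L], W2, d[3L]))
    dx[sort(unique(ri)), , ] <- array(gm, c(nrow(gm), W2, d[3L]))
    dxm <- rowsum(matrix(aperm(dx, c(2L, 1L, 3L)), W2, d[1L] * d[3L]), cj)
    dx2 <- array(0, c(d[2L], d[1L], d[3L]))
    dx2[sort(unique(cj)), , ] <- array(dxm, c(nrow(dxm), d[1L], d[3L]))
    ad_accum(x, aperm(dx2, c(2L, 1L, 3L)))
  })
}

ad_crop <- function(tape, x, H, W) {
  xv <- as_hwc(ad_value(x))
  d <- dim(xv)
  out <- xv[seq_len(H), seq_len(W), , drop = FALSE]
  ad_op(tape, out, function(g) {
    dx <- array(0, d)
    dx[seq_len(H), seq_len(W), ] <- g
    ad_accum(x, dx)
  })
}

# ---- losses -----------------------------------------------------------------

# Mean absolute error over pixels with weight > 0; y is a plain matrix.
ad_mae <- function(tape, yhat, y, weight) {
  yv <- ad_value(yhat)
  dim(yv) <- dim(y)
  wsum <- sum(weight)
  out <- sum(abs(yv - y) * weight) / wsum
  ad_op(tape, out, function(g) {
    dx <- g * sign(yv - y) * weight / wsum
    dim(dx) <- dim(ad_value(yhat))
    ad_accum(yhat, dx)
  })
}

# Fused per-pixel softmax + cross-entropy against integer class targets
# (0-based), averaged over pixels with weight > 0. Natural-log convention.
ad_softmax_ce <- function(tape, logits, target, weight) {
  lv <- as_hwc(ad_value(logits))
  d <- dim(lv); n <- d[1L] * d[2L]; K <- d[3L]
  mat <- matrix(lv, n, K)
  mx <- apply(mat, 1L, max)
  ex <- exp(mat - mx)
  Z <- rowSums(ex)
  tgt <- as.vector(target) + 1L
  logp <- (mat[cbind(seq_len(n), tgt)] - mx) - log(Z)
  wv <- as.vector(weight)
  wsum <- sum(wv)
  out <- -sum(logp * wv) / wsum
  ad_op(tape, out, function(g) {
    p <- ex / Z
    p[cbind(seq_len(n), tgt)] <- p[cbind(seq_len(n), tgt)] - 1
    dl <- array(p * (g * wv / wsum), d)
    ad_accum(logits, dl)
  })
}

# Plain per-pixel softmax along the class dimension (inference path).
softmax_hwk <- function(logits) {
  d <- dim(logits)
  mat <- matrix(logits, d[1L] * d[2L], d[3L])
  mx <- apply(mat, 1L, max)
  ex <- exp(mat - mx)
  array(ex / rowSums(ex), d)
}
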
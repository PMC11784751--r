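# Residual construction and the column maskings.
#
# The networks predict a plane Yhat (floating point, clamped to [0, 255]);
# what is entropy coded is the offset, quantized residual
#   R = Q(Y - Yhat + 255),  Q(x) = floor(x + 0.5),
# an integer in [0, 510] (511 classes). Because Q is invariant under integer
# translation, Y = R - Q(255 - Yhat) recovers the true pixel exactly when the
# decoder reproduces Yhat bit for bit.

q_round <- function(x) floor(x + 0.5)

#' Compute the 511-class quantized residual of a plane
#'
#' @param true Matrix of true pixels in `[0, 255]`.
#' @param pred Matrix of predicted pixels; clamped to `[0, 255]` first.
#' @return Integer matrix in `[0, 510]`.
#' @export
compute_residual <- function(true, pred) {
  if (!identical(dim(true), dim(pred))) stop("shape mismatch")
  pred <- pmin(pmax(pred, 0), 255)
  r <- q_round(true - pred + 255)
  if (any(!is.finite(r))) stop("non-finite residual: model fault")
  bad <- r < 0 | r > 510
  if (any(bad)) {
    warning("residual outside [0, 510] clipped: model fault")
    r <- pmin(pmax(r, 0), 510)
  }
  r
}

#' Invert a quantized residual back to true pixels
#'
#' Requires the identical prediction the encoder used.
#'
#' @param residual Integer matrix in `[0, 510]`.
#' @param pred The encoder's predicted plane (clamped to `[0, 255]`).
#' @return Matrix of pixels in `[0, 255]`.
#' @export
reconstruct_pixels <- function(residual, pred) {
  if (!identical(dim(residual), dim(pred))) stop("shape mismatch")
  pred <- pmin(pmax(pred, 0), 255)
  y <- residual - q_round(255 - pred)
  if (any(y < 0 | y > 255))
    stop("reconstructed pixel outside [0, 255]: corrupted stream or weight mismatch")
  y
}

col_parity_kept <- function(W, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  idx0 <- seq_len(W) - 1L
  if (parity == "even") idx0 %% 2L == 0L else idx0 %% 2L == 1L
}

#' Zero out the columns of one parity in a residual plane
#'
#' @param residual Integer matrix in `[0, 510]`.
#' @param keep `"even"` keeps the even (0-based) columns and zeroes the odd
#'   ones; `"odd"` the reverse.
#' @return Masked residual plane.
#' @export
mask_residual <- function(residual, keep = c("even", "odd")) {
  keep <- match.arg(keep)
  kept <- col_parity_kept(ncol(residual), keep)
  residual[, !kept] <- 0
  residual
}

#' Force the suppressed columns of a probability volume to class 0
#'
#' At columns of the suppressed parity the masked residual is identically 0,
#' so class 0 is given probability 1 and classes 1..510 probability 0; an
#' arithmetic coder then spends no bits on those pixels. Kept columns pass
#' through unchanged.
#'
#' @param prob Array `h x w x 511` of per-pixel class probabilities.
#' @param keep `"even"` or `"odd"`: the parity whose probabilities survive.
#' @return Masked probability volume (still a distribution at every pixel).
#' @export
mask_probability <- function(prob, keep = c("even", "odd")) {
  keep <- match.arg(keep)
  d <- dim(prob)
  stopifnot(length(d) == 3L, d[3L] == 511L)
  kept <- col_parity_kept(d[2L], keep)
  prob[, !kept, ] <- 0
  prob[, !kept, 1L] <- 1
  prob
}
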
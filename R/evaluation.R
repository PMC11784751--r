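# Evaluation: bits per pixel, probability heatmaps, probability-bin reports.

#' Bits per pixel of a compressed container
#'
#' @param bytes Raw container (or its byte length).
#' @param dims Optional `c(height, width)`; read from the container header
#'   when omitted.
#' @return `8 * bytes / (height * width)`.
#' @export
bpp <- function(bytes, dims = NULL) {
  nbytes <- if (is.raw(bytes)) length(bytes) else as.numeric(bytes)
  if (is.null(dims)) {
    if (!is.raw(bytes)) stop("dims required when only a byte count is given")
    cont <- read_container(bytes)
    dims <- c(cont$original_height, cont$original_width)
  }
  8 * nbytes / (dims[1L] * dims[2L])
}

#' Per-pixel probability of the actually observed residual
#'
#' For each pixel, looks up the model probability assigned to the residual
#' symbol that occurred; close to 1 means the symbol was cheap to code,
#' close to 0 means expensive.
#'
#' @param residual Integer matrix in `[0, 510]`.
#' @param prob Array `h x w x 511`.
#' @return Matrix of probabilities in `[0, 1]`.
#' @export
probability_heatmap <- function(residual, prob) {
  d <- dim(prob)
  if (!identical(dim(residual), d[1:2])) stop("shape mismatch")
  pm <- matrix(prob, d[1L] * d[2L], d[3L])
  matrix(pm[cbind(seq_len(d[1L] * d[2L]), as.vector(residual) + 1L)],
         d[1L], d[2L])
}

#' Write a probability heatmap as a red-to-green PNG
#'
#' Red marks probabilities near 0 (poorly coded pixels), green near 1.
#'
#' @param heatmap Matrix from [probability_heatmap()].
#' @param path Output PNG path.
#' @export
write_heatmap_png <- function(heatmap, path) {
  rgb <- array(0, c(nrow(heatmap), ncol(heatmap), 3L))
  rgb[, , 1L] <- 1 - heatmap
  rgb[, , 2L] <- heatmap
  png::writePNG(rgb, path)
  invisible(path)
}

#' Fractions of pixels per residual-probability bin
#'
#' Bins follow the diagnostic convention: high `P > 0.1`, mid
#' `0.01 <= P <= 0.1` (closed), low `P < 0.01`. Masked (probability-forced)
#' pixels should be excluded through `scope` so the report describes
#' genuinely coded symbols.
#'
#' @param heatmap Matrix of per-pixel probabilities.
#' @param scope Logical matrix of pixels to include (default all).
#' @return List of class `bin_report` with percentages `frac_high`,
#'   `frac_mid`, `frac_low` summing to 100.
#' @export
probability_bins <- function(heatmap, scope = NULL) {
  if (is.null(scope)) scope <- matrix(TRUE, nrow(heatmap), ncol(heatmap))
  v <- heatmap[scope]
  if (length(v) == 0L) stop("empty scope")
  structure(list(
    frac_high = 100 * mean(v > 0.1),
    frac_mid = 100 * mean(v >= 0.01 & v <= 0.1),
    frac_low = 100 * mean(v < 0.01),
    n = length(v)
  ), class = "bin_report")
}

#' @export
print.bin_report <- function(x, ...) {
  cat(sprintf("residual probability bins over %d pixels:\n", x$n))
  cat(sprintf("  P > 0.1        : %6.2f%%\n", x$frac_high))
  cat(sprintf("  0.01 <= P <= 0.1: %6.2f%%\n", x$frac_mid))
  cat(sprintf("  P < 0.01       : %6.2f%%\n", x$frac_low))
  invisible(x)
}
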
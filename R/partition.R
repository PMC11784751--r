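# Tree-structured subimage partitioning.
#
# Level 1 is a 2x2 polyphase ("quadtree") decomposition: the four subimages
# hold the pixels at (even row, even col), (even, odd), (odd, even) and
# (odd, odd) positions. Interleaved sampling keeps the four planes spatially
# aligned, so already-coded planes are strong priors for the remaining ones.
# Level 2 splits a plane into its even ("left") and odd ("right") columns.
# All indexing conventions below are 0-based when talking about parity.

#' Pad an image to even height and width
#'
#' Replicates the last row and/or column so both dimensions become even.
#' The caller records the original size (the container header does this) so
#' the padding can be cropped away after decoding.
#'
#' @param image Integer-valued matrix with values in `[0, 255]`.
#' @return A matrix with even dimensions.
#' @examples
#' pad_to_even(matrix(1:9, 3, 3))
#' @export
pad_to_even <- function(image) {
  image <- check_plane(image)
  H <- nrow(image); W <- ncol(image)
  if (H %% 2L == 1L) image <- rbind(image, image[H, , drop = FALSE])
  if (W %% 2L == 1L) image <- cbind(image, image[, W, drop = FALSE])
  image
}

check_plane <- function(image, range = c(0, 255)) {
  if (!is.matrix(image) || nrow(image) < 1L || ncol(image) < 1L)
    stop("image must be a non-empty matrix")
  if (anyNA(image) || any(image < range[1L]) || any(image > range[2L]))
    stop(sprintf("pixel values must lie in [%d, %d]", range[1L], range[2L]))
  storage.mode(image) <- "double"
  image
}

#' Split an image into four polyphase level-1 subimages
#'
#' @param image Matrix with even height and width.
#' @return List of class `subimage_set` with planes `a`, `b`, `c`, `d`
#'   (a = even row/even col, b = even/odd, c = odd/even, d = odd/odd,
#'   0-based parity), each of size `H/2 x W/2`.
#' @export
split_level1 <- function(image) {
  image <- check_plane(image)
  H <- nrow(image); W <- ncol(image)
  if (H %% 2L == 1L || W %% 2L == 1L)
    stop("split_level1 requires even dimensions; call pad_to_even first")
  er <- seq(1L, H, 2L); or <- seq(2L, H, 2L)
  ec <- seq(1L, W, 2L); oc <- seq(2L, W, 2L)
  structure(list(
    a = image[er, ec, drop = FALSE],
    b = image[er, oc, drop = FALSE],
    c = image[or, ec, drop = FALSE],
    d = image[or, oc, drop = FALSE]
  ), class = "subimage_set")
}

#' Reassemble an image from its four level-1 subimages
#'
#' Exact inverse of [split_level1()].
#'
#' @param parts A `subimage_set` (or plain list with planes `a`, `b`, `c`, `d`).
#' @return The interleaved `H x W` matrix.
#' @export
merge_level1 <- function(parts) {
  a <- parts$a; b <- parts$b; cc <- parts$c; d <- parts$d
  dm <- dim(a)
  if (!all(vapply(list(b, cc, d), function(p) identical(dim(p), dm), logical(1L))))
    stop("all four subimages must have identical shape")
  H <- 2L * dm[1L]; W <- 2L * dm[2L]
  out <- matrix(0, H, W)
  er <- seq(1L, H, 2L); or <- seq(2L, H, 2L)
  ec <- seq(1L, W, 2L); oc <- seq(2L, W, 2L)
  out[er, ec] <- a; out[er, oc] <- b
  out[or, ec] <- cc; out[or, oc] <- d
  out
}

#' Split a plane into its even- and odd-column halves
#'
#' The even columns (0-based indices 0, 2, 4, ...) form the "left" level-2
#' subimage, the odd columns the "right" one.
#'
#' @param plane Matrix with even width.
#' @return List of class `column_split` with `left` and `right` matrices.
#' @export
split_columns <- function(plane) {
  if (!is.matrix(plane)) stop("plane must be a matrix")
  W <- ncol(plane)
  if (W %% 2L == 1L) stop("split_columns requires even width")
  structure(list(
    left = plane[, seq(1L, W, 2L), drop = FALSE],
    right = plane[, seq(2L, W, 2L), drop = FALSE]
  ), class = "column_split")
}

#' Interleave two column halves back into one plane
#'
#' Exact inverse of [split_columns()].
#'
#' @param split A `column_split` (or list with `left` and `right`).
#' @return The merged matrix.
#' @export
merge_columns <- function(split) {
  left <- split$left; right <- split$right
  if (!identical(dim(left), dim(right)))
    stop("left and right halves must have identical shape")
  W <- 2L * ncol(left)
  out <- matrix(0, nrow(left), W)
  out[, seq(1L, W, 2L)] <- left
  out[, seq(2L, W, 2L)] <- right
  out
}
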
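# Image file readers/writers: 8-bit grayscale PNG (via the png package) and
# PGM (both binary P5 and ASCII P2; the format is simple enough that no
# dependency provides a lighter path).

#' Read an 8-bit grayscale image file
#'
#' Supports PNG (color inputs are reduced to their first channel) and PGM
#' (P2/P5, maxval <= 255).
#'
#' @param path File path; format chosen by extension.
#' @return Integer-valued pixel matrix in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    round(img * 255)
  } else if (ext %in% c("pgm", "pnm")) {
    read_pgm(path)
  } else stop("unsupported image format: ", ext)
}

#' Write an 8-bit grayscale image file
#'
#' @param image Pixel matrix in `[0, 255]`.
#' @param path Output path ending in .png or .pgm.
#' @export
write_image <- function(image, path) {
  image <- check_plane(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image / 255, path)
  } else if (ext %in% c("pgm", "pnm")) {
    write_pgm(image, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  toks <- character(0)
  # header: magic, width, height, maxval with '#' comments allowed
  while (length(toks) < 4L) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PGM header")
    line <- sub("#.*$", "", line)
    toks <- c(toks, strsplit(trimws(line), "[[:space:]]+")[[1L]])
    toks <- toks[nzchar(toks)]
  }
  magic <- toks[1L]
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L]); maxval <- as.integer(toks[4L])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file")
  if (is.na(maxval) || maxval > 255L) stop("only maxval <= 255 supported")
  if (magic == "P5") {
    px <- as.integer(readBin(con, "raw", h * w))
    if (length(px) < h * w) stop("truncated PGM payload")
  } else {
    px <- scan(con, what = integer(), n = h * w, quiet = TRUE)
  }
  matrix(px, h, w, byrow = TRUE)
}

write_pgm <- function(image, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(image), nrow(image)), "255"), con, sep = "\n")
  writeBin(as.raw(as.integer(t(image))), con)
  invisible(path)
}
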
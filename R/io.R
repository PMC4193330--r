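# Image and mask I/O: PNG via the png package, plain-text PGM (P2) for
# fixtures and external tools, and run-length encoding for masks.

#' Write a matrix as a grayscale PNG
#' @param M numeric matrix; values are clamped to \[0, 1\].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_gray_png <- function(M, file) {
  png::writePNG(pmin(pmax(M, 0), 1), file)
  invisible(file)
}

#' Write a signed field as a diverging-colour PNG
#'
#' Positive values in warm colours, negative in blue, zero in black; scaled
#' by the largest absolute value.
#'
#' @param M numeric matrix.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_signed_png <- function(M, file) {
  a <- max(abs(M), 1e-12)
  pos <- pmax(M, 0) / a
  neg <- pmax(-M, 0) / a
  rgb <- array(0, c(nrow(M), ncol(M), 3))
  rgb[, , 1] <- pos
  rgb[, , 2] <- pos * 0.5
  rgb[, , 3] <- neg
  png::writePNG(rgb, file)
  invisible(file)
}

#' Read a grayscale image (PNG) into a \[0, 1\] matrix
#' @param file path to a PNG file.
#' @return numeric matrix.
#' @export
read_gray_png <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a matrix as a plain-text PGM (P2)
#' @param M numeric matrix in \[0, 1\].
#' @param file output path.
#' @param maxval maximum gray level.
#' @return the file path, invisibly.
#' @export
write_pgm <- function(M, file, maxval = 255L) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(M), nrow(M)), as.character(maxval)), con)
  vals <- round(pmin(pmax(M, 0), 1) * maxval)
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a plain-text PGM (P2) into a \[0, 1\] matrix
#' @param file path to a P2 PGM file.
#' @return numeric matrix.
#' @export
read_pgm <- function(file) {
  txt <- readLines(file)
  txt <- txt[!grepl("^#", txt)]
  toks <- scan(text = paste(txt[-1], collapse = " "), quiet = TRUE)
  if (trimws(txt[1]) != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  matrix(toks[-(1:3)], nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Run-length encode a logical mask
#' @param mask logical matrix.
#' @return list with `dim` and integer `runs` (lengths of alternating
#'   FALSE/TRUE runs in column-major order, starting with FALSE).
#' @export
mask_to_rle <- function(mask) {
  stop_if_not_mask(mask)
  r <- rle(as.vector(mask))
  if (r$values[1]) {
    r$lengths <- c(0L, r$lengths)
    r$values <- c(FALSE, r$values)
  }
  list(dim = dim(mask), runs = as.integer(r$lengths))
}

#' Decode a run-length encoded mask
#' @param x a [mask_to_rle()] list.
#' @return logical matrix.
#' @export
rle_to_mask <- function(x) {
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(x$runs)), x$runs)
  matrix(vals, x$dim[1], x$dim[2])
}

#' Load an external grayscale image as a display
#'
#' Thresholds a user-supplied image into a figure mask so natural images can
#' be pushed through the model as a demonstration; no ground-truth skeleton
#' quality is implied for such inputs.
#'
#' @param file PNG path.
#' @param threshold figure/background cut in \[0, 1\].
#' @param invert treat dark pixels as figure.
#' @return a `visual_display`.
#' @export
load_image_display <- function(file, threshold = 0.5, invert = FALSE) {
  img <- read_gray_png(file)
  mask <- if (invert) img < threshold else img >= threshold
  new_visual_display(img, mask, name = basename(file),
                     params = list(file = file, threshold = threshold,
                                   invert = invert))
}
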
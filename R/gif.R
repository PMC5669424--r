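# R-side interface to the pinned GIF87a/LZW encoder.

#' Encode a raster matrix as GIF
#'
#' Uses the package's pinned GIF87a encoder with a grayscale palette.
#' Binary images (all values 0/1) are encoded with a 2-colour palette;
#' anything else is linearly quantized to 8-bit (256 gray levels).
#'
#' @param img Numeric matrix; values outside \[0, 1\] are allowed for edge
#'   maps and are normalized by the maximum before quantization.
#' @return A raw vector holding the GIF byte stream.
#' @export
gif_encode <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (all(img == 0 | img == 1)) {
    idx <- img
    ncolors <- 2L
  } else {
    mx <- max(img)
    idx <- if (mx > 0) round(255 * img / mx) else img * 0
    ncolors <- 256L
  }
  # GIF scan order is row-major
  gif_encode_cpp(as.integer(t(idx)), ncol(img), nrow(img), ncolors)
}

#' Write a raster matrix to a GIF file
#'
#' @param img Numeric matrix (see [gif_encode()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_gif <- function(img, path) {
  writeBin(gif_encode(img), path)
  invisible(path)
}
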
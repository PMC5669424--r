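# Raster images are plain numeric matrices with intensities in [0, 1]
# (0 = black, 1 = white). Patterns are binary.

#' Validate and coerce a raster image
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param binary Require all values to be exactly 0 or 1.
#' @param square Require a square matrix.
#' @return The validated matrix (invisibly unchanged).
#' @keywords internal
check_raster <- function(img, binary = FALSE, square = FALSE) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  if (binary && !all(img == 0 | img == 1))
    stop("image must be binary (all values 0 or 1)", call. = FALSE)
  if (square && nrow(img) != ncol(img))
    stop("image must be square", call. = FALSE)
  invisible(img)
}

#' Rotate a matrix 90 degrees counter-clockwise
#'
#' @param m A matrix.
#' @return The rotated matrix.
#' @export
rot90 <- function(m) {
  t(m)[ncol(m):1, , drop = FALSE]
}

#' Mirror an image across one of the four symmetry axes
#'
#' Reflections: `"vertical"` flips left-right, `"horizontal"` flips
#' top-bottom, `"main_diagonal"` transposes, `"secondary_diagonal"`
#' anti-transposes (square images only for the diagonals).
#'
#' @param img A matrix.
#' @param axis One of `"vertical"`, `"horizontal"`, `"main_diagonal"`,
#'   `"secondary_diagonal"`.
#' @return The reflected matrix.
#' @export
reflect_image <- function(img, axis = c("vertical", "horizontal",
                                        "main_diagonal", "secondary_diagonal")) {
  axis <- match.arg(axis)
  if (axis %in% c("main_diagonal", "secondary_diagonal") &&
      nrow(img) != ncol(img))
    stop("diagonal reflection requires a square image", call. = FALSE)
  switch(axis,
    vertical           = img[, ncol(img):1, drop = FALSE],
    horizontal         = img[nrow(img):1, , drop = FALSE],
    main_diagonal      = t(img),
    secondary_diagonal = t(img)[ncol(img):1, nrow(img):1, drop = FALSE]
  )
}

#' Read an image file as a grayscale raster matrix
#'
#' Reads PNG, TIFF or JPEG and converts to a single-channel intensity
#' matrix by averaging colour channels.
#'
#' @param path Path to a `.png`, `.tif(f)` or `.jp(e)g` file.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (is.list(arr)) arr <- arr[[1]]
  if (length(dim(arr)) == 3) {
    nch <- min(dim(arr)[3], 3)  # drop alpha
    arr <- apply(arr[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  arr
}

#' Write a raster matrix as a lossless PNG
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  check_raster(img)
  png::writePNG(img, path)
  invisible(path)
}
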
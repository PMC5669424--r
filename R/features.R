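# The 24-predictor battery: file-compression ratios, edge-operator
# statistics, and structural measures of balance, centre of mass,
# symmetry and homogeneity. "Black" pixels are intensities < 0.5.

#' Registry of the 24 predictor names
#' @export
PREDICTOR_NAMES <- c(
  "GIF", "PNG", "TIF", "JPG",
  "PHCMN", "PHCSD", "PHCMNSD",
  "CANMN", "CANSD", "CANMNSD",
  "PERMN", "PERSD", "PERMNSD",
  "RMSMN", "RMSSD", "RMSMNSD",
  "PHCGIF", "CANGIF", "PERGIF", "RMSGIF",
  "APB", "DCM", "MS", "HG"
)

# byte count of one encoding
encode_bytes <- function(img, codec) {
  switch(codec,
    GIF = length(gif_encode(img)),
    PNG = length(png::writePNG(img, raw())),
    TIF = {
      f <- tempfile(fileext = ".tif")
      on.exit(unlink(f))
      tiff::writeTIFF(img, f, compression = "LZW")
      file.size(f)
    },
    JPG = length(jpeg::writeJPEG(img, raw(), quality = 0.9)),
    stop("unknown codec: ", codec, call. = FALSE)
  )
}

#' Compression ratio of an image (two-orientation mean)
#'
#' Bytes-per-pixel of the encoded image, averaged over the original and a
#' 90-degree rotated copy (compression can differ between orientations).
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param codec `"GIF"`, `"PNG"`, `"TIF"` (LZW) or `"JPG"` (quality 90).
#' @param orientations Return the per-orientation ratios as an attribute.
#' @return Mean compressed bytes per pixel.
#' @export
compression_ratio <- function(img, codec = c("GIF", "PNG", "TIF", "JPG"),
                              orientations = FALSE) {
  codec <- match.arg(codec)
  check_raster(img)
  npix <- length(img)
  bh <- encode_bytes(img, codec)
  bv <- encode_bytes(rot90(img), codec)
  out <- (bh + bv) / (2 * npix)
  if (orientations)
    attr(out, "orientations") <- c(H = bh / npix, V = bv / npix)
  out
}

#' Edge map of an image
#'
#' Four operators: `"PHC"` phase congruency (log-Gabor formulation,
#' continuous magnitude in \[0, 1\]); `"CAN"` binary Canny edges (Gaussian
#' sigma 1, Otsu-derived high threshold, low = 0.4 high); `"PER"` binary
#' boundary pixels of black regions under 4-connectivity (image border
#' treated as background); `"RMS"` local root-mean-square contrast (sliding
#' window population SD divided by mean image intensity).
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param method One of `"PHC"`, `"CAN"`, `"PER"`, `"RMS"`.
#' @param rms_window Odd window size for the RMS operator (default 5).
#' @return Object of class `edge_map`: list with `values` (matrix, CAN and
#'   PER binary) and `method`.
#' @export
edge_map <- function(img, method = c("PHC", "CAN", "PER", "RMS"),
                     rms_window = 5L) {
  method <- match.arg(method)
  check_raster(img)
  v <- switch(method,
    PHC = phase_congruency(img),
    CAN = canny_edges(img),
    PER = perimeter_edges(img),
    RMS = rms_contrast(img, window = rms_window)
  )
  structure(list(values = v, method = method), class = "edge_map")
}

#' Mean, SD and their product for an edge map
#'
#' @param e An `edge_map` (or plain matrix).
#' @return Named vector `c(MN, SD, MNSD)`; SD is the population standard
#'   deviation.
#' @export
edge_stats <- function(e) {
  v <- if (inherits(e, "edge_map")) e$values else e
  mn <- mean(v)
  sdv <- sqrt(mean((v - mn)^2))
  c(MN = mn, SD = sdv, MNSD = mn * sdv)
}

#' GIF compression ratio of an edge map
#'
#' Continuous maps are linearly quantized to 8-bit before encoding; binary
#' maps use a 2-colour palette (identical byte stream either way for 0/1
#' inputs). The ratio is the two-orientation mean, as for
#' [compression_ratio()].
#'
#' @param e An `edge_map` (or plain matrix).
#' @return Mean compressed bytes per pixel.
#' @export
edge_gif <- function(e) {
  v <- if (inherits(e, "edge_map")) e$values else e
  npix <- length(v)
  (length(gif_encode(v)) + length(gif_encode(rot90(v)))) / (2 * npix)
}

black_mask <- function(img) img < 0.5

#' Deviation of the centre of mass
#'
#' Euclidean distance between the centroid of black pixels and the image
#' centre, normalized by the half-diagonal of the pixel-centre bounding
#' box so a single corner pixel scores 1.
#'
#' @param img Numeric matrix with at least one black (< 0.5) pixel.
#' @return Score in \[0, 1\].
#' @export
dcm <- function(img) {
  b <- black_mask(img)
  if (!any(b)) stop("all-white image: centroid undefined", call. = FALSE)
  m <- nrow(img); w <- ncol(img)
  ij <- which(b, arr.ind = TRUE)
  cy <- mean(ij[, 1]); cx <- mean(ij[, 2])
  d <- sqrt((cy - (m + 1) / 2)^2 + (cx - (w + 1) / 2)^2)
  d / (sqrt((m - 1)^2 + (w - 1)^2) / 2)
}

#' Assessment of preference for balance
#'
#' For each of eight axes through the image centre (vertical, horizontal,
#' the two diagonals and the four intermediate 22.5-degree axes) the
#' absolute difference in black-pixel mass between the two half-planes is
#' taken relative to total black mass; `APB = 100 - 200 * mean(imbalance)`,
#' so perfectly balanced images score 100. Pixels whose centre lies on an
#' axis are split evenly.
#'
#' @param img Numeric matrix with at least one black pixel.
#' @return Score (maximum 100).
#' @export
apb <- function(img) {
  b <- black_mask(img)
  if (!any(b)) stop("all-white image: balance undefined", call. = FALSE)
  m <- nrow(img); w <- ncol(img)
  ij <- which(b, arr.ind = TRUE)
  y <- ij[, 1] - (m + 1) / 2
  x <- ij[, 2] - (w + 1) / 2
  total <- nrow(ij)
  angles <- (0:7) * pi / 8
  imbalance <- vapply(angles, function(th) {
    s <- x * sin(th) - y * cos(th)
    abs(sum(sign(s))) / total  # on-axis pixels (s == 0) contribute 0
  }, numeric(1))
  100 - 200 * mean(imbalance)
}

#' Homogeneity (relative entropy of block-wise black mass)
#'
#' The image is partitioned into an 8 x 8 block grid; the Shannon entropy
#' of the black-mass distribution over blocks, divided by log(64), gives a
#' score of 1 for perfectly even mass and 0 for mass concentrated in a
#' single block.
#'
#' @param img Numeric matrix with at least one black pixel.
#' @param blocks Blocks per side (default 8).
#' @return Score in \[0, 1\].
#' @export
homogeneity <- function(img, blocks = 8L) {
  b <- black_mask(img)
  if (!any(b)) stop("all-white image: homogeneity undefined", call. = FALSE)
  m <- nrow(img); w <- ncol(img)
  ij <- which(b, arr.ind = TRUE)
  br <- pmin(blocks, ceiling(ij[, 1] / (m / blocks)))
  bc <- pmin(blocks, ceiling(ij[, 2] / (w / blocks)))
  p <- tabulate((br - 1L) * blocks + bc, nbins = blocks * blocks)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(blocks^2)
}

#' Compute the full 24-predictor vector of an image
#'
#' Combines the four compression ratios, the twelve edge-map statistics,
#' the four edge-map GIF ratios and the four structural measures, plus the
#' per-axis symmetry scores `MSA`..`MSD` (unit scale).
#'
#' @param img Square binary numeric matrix.
#' @param rms_window RMS-contrast window size.
#' @param orientations Also emit the separate per-orientation columns
#'   (`HGIF`/`VGIF`, ...) behind the orientation-averaged compression
#'   ratios.
#' @return A named numeric vector with the 24 predictors and `MSA`..`MSD`
#'   (plus the `H...`/`V...` orientation columns when requested).
#' @export
extract_all <- function(img, rms_window = 5L, orientations = FALSE) {
  check_raster(img, binary = TRUE, square = TRUE)
  out <- numeric(0)
  hv <- numeric(0)
  for (codec in c("GIF", "PNG", "TIF", "JPG")) {
    r <- compression_ratio(img, codec, orientations = TRUE)
    out[codec] <- as.numeric(r)
    o <- attr(r, "orientations")
    hv[paste0(c("H", "V"), codec)] <- o
  }
  for (mth in c("PHC", "CAN", "PER", "RMS")) {
    e <- edge_map(img, mth, rms_window = rms_window)
    st <- edge_stats(e)
    out[paste0(mth, c("MN", "SD", "MNSD"))] <- st
    out[paste0(mth, "GIF")] <- edge_gif(e)
  }
  out["APB"] <- apb(img)
  out["DCM"] <- dcm(img)
  prof <- mirror_symmetry(img)
  out["MS"] <- prof$ms
  out["HG"] <- homogeneity(img)
  out[names(MS_AXIS_COLS)] <- prof$axes[MS_AXIS_COLS]
  out <- out[c(PREDICTOR_NAMES, names(MS_AXIS_COLS))]
  if (orientations) out <- c(out, hv)
  out
}
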
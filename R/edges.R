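# Edge operators. Implemented directly on matrices; convolution uses
# reflective padding so operator output has the same shape as the input.

# Pad a matrix by k pixels on each side, reflecting across the border.
pad_reflect <- function(img, k) {
  m <- nrow(img); w <- ncol(img)
  ri <- c(rev(seq_len(min(k, m))), seq_len(m), m + 1 - seq_len(min(k, m)))
  ci <- c(rev(seq_len(min(k, w))), seq_len(w), w + 1 - seq_len(min(k, w)))
  img[ri, ci, drop = FALSE]
}

# 2-D convolution with a small kernel, reflective borders, "same" output.
conv2_same <- function(img, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  rr <- (kr - 1L) %/% 2L; rc <- (kc - 1L) %/% 2L
  p <- pad_reflect(img, max(rr, rc))
  off <- max(rr, rc)
  m <- nrow(img); w <- ncol(img)
  out <- matrix(0, m, w)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    if (kern[i, j] == 0) next
    out <- out + kern[i, j] *
      p[(off - rr + i - 1L) + seq_len(m), (off - rc + j - 1L) + seq_len(w)]
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Box-filter local mean via padded cumulative sums (population moments).
box_mean <- function(img, k) {
  r <- (k - 1L) %/% 2L
  p <- pad_reflect(img, r)
  cs <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  m <- nrow(img); w <- ncol(img)
  Z <- matrix(0, nrow(cs) + 1L, ncol(cs) + 1L)
  Z[-1, -1] <- cs
  i1 <- seq_len(m); j1 <- seq_len(w)
  (Z[i1 + 2L * r + 1L, j1 + 2L * r + 1L, drop = FALSE] -
     Z[i1, j1 + 2L * r + 1L, drop = FALSE] -
     Z[i1 + 2L * r + 1L, j1, drop = FALSE] +
     Z[i1, j1, drop = FALSE]) / (k * k)
}

# Otsu threshold of a non-negative matrix (256-bin histogram).
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  mx <- max(v)
  if (mx == 0) return(0)
  h <- tabulate(pmin(256L, 1L + floor(255 * v / mx)), nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  (k / 256) * mx
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression, hysteresis with Otsu-derived high threshold, low = 0.4 high.
canny_edges <- function(img, sigma = 1, low_frac = 0.4) {
  g1 <- gaussian_kernel_1d(sigma)
  sm <- conv2_same(conv2_same(img, matrix(g1, ncol = 1)), matrix(g1, nrow = 1))
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2_same(sm, sx)
  gy <- conv2_same(sm, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  mag[mag < 1e-9] <- 0  # suppress float dust from flat regions
  if (max(mag) == 0) return(matrix(0, nrow(img), ncol(img)))

  # non-maximum suppression in 4 quantized gradient directions
  ang <- atan2(gy, gx)
  sector <- floor(((ang + pi) / (pi / 4)) %% 4)  # 0 E-W, 1 NE-SW, 2 N-S, 3 NW-SE
  m <- nrow(img); w <- ncol(img)
  pm <- pad_reflect(mag, 1L)
  shift <- function(di, dj) pm[1L + di + seq_len(m), 1L + dj + seq_len(w)]
  n1 <- matrix(0, m, w); n2 <- n1
  for (s in 0:3) {
    d <- switch(s + 1L,
      list(c(0, 1), c(0, -1)),
      list(c(-1, 1), c(1, -1)),
      list(c(1, 0), c(-1, 0)),
      list(c(1, 1), c(-1, -1)))
    sel <- sector == s
    n1[sel] <- shift(d[[1]][1], d[[1]][2])[sel]
    n2[sel] <- shift(d[[2]][1], d[[2]][2])[sel]
  }
  peak <- mag >= n1 & mag >= n2 & mag > 0

  high <- otsu_threshold(mag[peak])
  low <- low_frac * high
  strong <- peak & mag >= high
  weak <- peak & mag >= low
  if (!any(strong)) return(matrix(0, m, w))
  # hysteresis: keep weak components that contain a strong pixel
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  out <- matrix(0, m, w)
  out[weak & (lab %in% keep)] <- 1
  out
}

# Perimeter pixels of black regions: a black pixel is boundary if any
# 4-neighbour is background; the image border counts as background.
perimeter_edges <- function(img) {
  b <- black_mask(img)
  m <- nrow(img); w <- ncol(img)
  p <- matrix(FALSE, m + 2L, w + 2L)
  p[2:(m + 1), 2:(w + 1)] <- b
  i <- 2:(m + 1); j <- 2:(w + 1)
  interior <- p[i - 1, j] & p[i + 1, j] & p[i, j - 1] & p[i, j + 1]
  out <- matrix(0, m, w)
  out[b & !interior] <- 1
  out
}

# Local RMS contrast: population SD in a k x k sliding window divided by
# the mean intensity of the whole image.
rms_contrast <- function(img, window = 5L) {
  k <- as.integer(window)
  if (k < 1L || k %% 2L == 0L)
    stop("RMS window must be a positive odd integer", call. = FALSE)
  mu <- box_mean(img, k)
  mu2 <- box_mean(img^2, k)
  sdv <- sqrt(pmax(mu2 - mu^2, 0))  # first arg keeps matrix dims
  gm <- mean(img)
  if (gm == 0) return(sdv * 0)
  sdv / gm
}
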
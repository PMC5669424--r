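# Independent brute-force oracles. These enumerate every reflected pixel
# pair explicitly with loops and must stay independent of the package's
# vectorized implementations.

brute_axis_symmetry <- function(img, axis) {
  m <- nrow(img); w <- ncol(img)
  num <- 0; den <- 0
  if (axis == "vertical") {
    n <- w %/% 2
    for (i in seq_len(m)) for (j in seq_len(n)) {
      wt <- if (n == 1) 1 else 1 + (j - 1) / (n - 1)
      num <- num + wt * (img[i, j] == img[i, w + 1 - j])
      den <- den + wt
    }
  } else if (axis == "horizontal") {
    n <- m %/% 2
    for (i in seq_len(n)) for (j in seq_len(w)) {
      wt <- if (n == 1) 1 else 1 + (i - 1) / (n - 1)
      num <- num + wt * (img[i, j] == img[m + 1 - i, j])
      den <- den + wt
    }
  } else if (axis == "main_diagonal") {
    stopifnot(m == w)
    nd <- w - 1
    for (i in seq_len(w)) for (j in seq_len(w)) {
      if (j <= i) next
      d <- j - i
      wt <- if (nd == 1) 1 else 1 + (nd - d) / (nd - 1)
      num <- num + wt * (img[i, j] == img[j, i])
      den <- den + wt
    }
  } else if (axis == "secondary_diagonal") {
    stopifnot(m == w)
    nd <- w - 1
    for (i in seq_len(w)) for (j in seq_len(w)) {
      if (i + j <= w + 1) next  # one side of the anti-diagonal
      d <- i + j - (w + 1)
      wt <- if (nd == 1) 1 else 1 + (nd - d) / (nd - 1)
      num <- num + wt * (img[i, j] == img[w + 1 - j, w + 1 - i])
      den <- den + wt
    }
  } else stop("unknown axis")
  num / den
}

brute_mirror_ms <- function(img) {
  axes <- c("vertical", "horizontal", "main_diagonal", "secondary_diagonal")
  100 * mean(vapply(axes, function(a) brute_axis_symmetry(img, a), numeric(1)))
}

# Two-pass arithmetic oracle for edge-map statistics.
brute_edge_stats <- function(v) {
  n <- length(v)
  mn <- sum(v) / n
  sdv <- sqrt(sum((v - mn)^2) / n)
  c(MN = mn, SD = sdv, MNSD = mn * sdv)
}

# Normal-equations oracle for OLS coefficients.
brute_ols_coef <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

random_binary <- function(m, w, p = 0.5) {
  matrix(as.numeric(runif(m * w) < p), m, w)
}
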
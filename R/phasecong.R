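# Phase congruency (log-Gabor formulation).
#
# Points of high phase congruency — where Fourier components of many
# scales arrive in phase — mark edges and corners independently of
# contrast. This implements the standard multi-scale, multi-orientation
# log-Gabor construction: per orientation, even/odd filter responses over
# scales give local amplitude and energy; energy is noise-thresholded and
# weighted by the spread of frequencies present; the map is the summed
# thresholded energy divided by the summed amplitude.

PHC_DEFAULTS <- list(
  nscale = 4L,        # number of wavelet scales
  norient = 6L,       # number of filter orientations
  min_wavelength = 3, # wavelength of smallest-scale filter (pixels)
  mult = 2.1,         # scaling factor between successive filters
  sigma_onf = 0.55,   # bandwidth of log-Gabor transfer function
  k = 2,              # no. of noise SDs for the energy threshold
  cut_off = 0.5,      # frequency-spread weighting cut-off
  g = 10,             # weighting sigmoid gain
  epsilon = 1e-4
)

# Low-pass filter (in the frequency domain) used to suppress boundary
# artefacts in the log-Gabor radial component.
lowpass_filter <- function(rho, cutoff = 0.45, n = 15) {
  1 / (1 + (rho / cutoff)^(2 * n))
}

phase_congruency <- function(img, params = PHC_DEFAULTS) {
  p <- utils::modifyList(PHC_DEFAULTS, params)
  rows <- nrow(img); cols <- ncol(img)

  # normalized frequency coordinates, DC at [1,1] to match fft layout
  fx <- ((seq_len(cols) - 1) - ifelse(seq_len(cols) - 1 > cols / 2, cols, 0)) / cols
  fy <- ((seq_len(rows) - 1) - ifelse(seq_len(rows) - 1 > rows / 2, rows, 0)) / rows
  u <- matrix(fx, rows, cols, byrow = TRUE)
  v <- matrix(fy, rows, cols)
  rho <- sqrt(u^2 + v^2)
  rho[1, 1] <- 1  # avoid log(0) at DC
  theta <- atan2(-v, u)
  lp <- lowpass_filter(rho)

  IMG <- fft(img)
  sin_t <- sin(theta); cos_t <- cos(theta)

  pc_sum <- matrix(0, rows, cols)

  for (o in seq_len(p$norient)) {
    angl <- (o - 1) * pi / p$norient
    ds <- sin_t * cos(angl) - cos_t * sin(angl)
    dc <- cos_t * cos(angl) + sin_t * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    # cosine-shaped angular spread, half-width pi/norient scaled
    dtheta <- pmin(dtheta * p$norient / 2, pi)
    spread <- (cos(dtheta) + 1) / 2

    sumE <- matrix(0, rows, cols)
    sumO <- matrix(0, rows, cols)
    sumAn <- matrix(0, rows, cols)
    maxAn <- matrix(0, rows, cols)
    tau <- NULL
    eL <- vector("list", p$nscale)
    oL <- vector("list", p$nscale)

    for (s in seq_len(p$nscale)) {
      wavelength <- p$min_wavelength * p$mult^(s - 1)
      fo <- 1 / wavelength
      log_gabor <- exp(-(log(rho / fo))^2 / (2 * log(p$sigma_onf)^2)) * lp
      log_gabor[1, 1] <- 0
      filt <- log_gabor * spread
      resp <- fft(IMG * filt, inverse = TRUE) / length(img)
      e <- Re(resp); odd <- Im(resp)
      eL[[s]] <- e; oL[[s]] <- odd
      An <- sqrt(e^2 + odd^2)
      sumE <- sumE + e
      sumO <- sumO + odd
      sumAn <- sumAn + An
      maxAn <- pmax(maxAn, An)
      if (s == 1)  # Rayleigh-median estimate of the noise amplitude
        tau <- stats::median(An) / sqrt(log(4))
    }

    # mean phase vector and the phase-deviation energy measure
    XEnergy <- sqrt(sumE^2 + sumO^2) + p$epsilon
    meanE <- sumE / XEnergy
    meanO <- sumO / XEnergy
    energy <- matrix(0, rows, cols)
    for (s in seq_len(p$nscale)) {
      e <- eL[[s]]; odd <- oL[[s]]
      energy <- energy + e * meanE + odd * meanO - abs(e * meanO - odd * meanE)
    }

    # noise threshold: total noise energy over scales follows from the
    # geometric amplitude decay between scales
    totalTau <- tau * (1 - (1 / p$mult)^p$nscale) / (1 - 1 / p$mult)
    noise_mean <- totalTau * sqrt(pi / 2)
    noise_sd <- totalTau * sqrt((4 - pi) / 2)
    T_thr <- noise_mean + p$k * noise_sd
    energy <- pmax(energy - T_thr, 0)

    # frequency-spread weighting
    width <- (sumAn / (maxAn + p$epsilon) - 1) / (p$nscale - 1)
    weight <- 1 / (1 + exp(p$g * (p$cut_off - width)))

    pc_sum <- pc_sum + weight * energy / (sumAn + p$epsilon)
  }

  pc <- pc_sum / p$norient
  pmin(pmax(pc, 0), 1)
}
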
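# Small shared numerics.

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # FWHM = 2.3548 sigma for a Gaussian

gaussian_profile <- function(x, centre, fwhm) {
  s <- fwhm / FWHM_SIGMA
  exp(-((x - centre)^2) / (2 * s^2))
}

# 1D full width at half maximum from sampled profile, linear interpolation
# of the half-maximum crossings. Returns NA when the profile does not fall
# below half maximum on both sides.
fwhm_interp <- function(x, y) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  left <- NA_real_
  if (i0 > 1) {
    for (i in i0:2) {
      if (y[i - 1] <= half && y[i] > half) {
        left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
        break
      }
    }
  }
  right <- NA_real_
  if (i0 < length(y)) {
    for (i in i0:(length(y) - 1)) {
      if (y[i + 1] <= half && y[i] > half) {
        right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
        break
      }
    }
  }
  right - left
}

# Separable Gaussian blur of a 2D image (rows = y, cols = x), zero-padded
# edges, kernel truncated at 4 sigma. Linear in the image.
blur_gaussian_2d <- function(img, sigma_y, sigma_x) {
  img <- blur_1d(img, sigma_y, along_rows = TRUE)
  blur_1d(img, sigma_x, along_rows = FALSE)
}

blur_1d <- function(img, sigma, along_rows) {
  if (sigma <= 1e-6) return(img)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- if (along_rows) nrow(img) else ncol(img)
  # banded convolution matrix, zero padding outside
  cm <- matrix(0, n, n)
  for (j in -r:r) {
    idx <- seq_len(n)
    tgt <- idx + j
    ok <- tgt >= 1 & tgt <= n
    cm[cbind(tgt[ok], idx[ok])] <- cm[cbind(tgt[ok], idx[ok])] + k[j + r + 1]
  }
  if (along_rows) cm %*% img else img %*% t(cm)
}

# n-dimensional circular convolution via FFT; kernel given centred.
fft_convolve <- function(x, kernel_centred) {
  d <- dim(x)
  k <- array(0, d)
  kd <- dim(kernel_centred)
  idx <- lapply(seq_along(d), function(i) seq_len(kd[i]))
  k[idx[[1]], idx[[2]], idx[[3]]] <- kernel_centred
  # roll so the kernel centre sits at the [1,1,1] origin
  ctr <- (kd + 1) %/% 2
  for (i in seq_along(d)) {
    sh <- ctr[i] - 1
    if (sh > 0) {
      perm <- c(seq(sh + 1, d[i]), seq_len(sh))
      k <- switch(i,
                  k[perm, , , drop = FALSE],
                  k[, perm, , drop = FALSE],
                  k[, , perm, drop = FALSE])
    }
  }
  re <- Re(fft(fft(x) * fft(k), inverse = TRUE)) / prod(d)
  re
}
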
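# V1-like input filter bank.
#
# Each filter is an oriented difference of two Gaussians (centre minus
# broader surround, along the axis perpendicular to the preferred
# orientation) weighted by a third, orthogonal Gaussian envelope along the
# preferred orientation.  The bank spans 4 spatial frequencies (octave
# spaced, 0.0625..0.5 cycles/pixel), 4 orientations (0..135 deg in 45 deg
# steps) and 2 signs (+1/-1), i.e. 32 channels.  The +/- sign channels carry
# the rectified positive and negative parts of the same linear response,
# mimicking on/off simple cells.
#
# The free constants of the construction are gathered in one block below:
# the centre width is chosen so the filter's passband peaks at its nominal
# frequency, the surround is sqrt(2) wider than the centre, and the envelope
# is 3x the centre width.  Acceptance of the model does not hinge on these
# exact values; they are the declared convention.
.filter_constants <- list(
  frequencies  = c(0.0625, 0.125, 0.25, 0.5),   # cycles/pixel
  orientations = c(0, 45, 90, 135),             # degrees
  signs        = c(1, -1),
  # centre sigma such that the 1-D DoG passband peaks at f (cycles/pixel)
  centre_sigma  = function(f) sqrt(log(2) / (2 * pi^2)) / f,
  surround_ratio = sqrt(2),
  envelope_ratio = 3,
  truncation     = 3,                           # kernel half-size, in envelope sigmas
  # per-band gain denominators (frequency ascending): mean L2 band energy of
  # the default cartoon-face ensemble, frozen so band equalisation never
  # depends on the current image
  band_gain      = c(125.9, 77.3, 37.4, 15.0)
)

#' Filter bank channel table
#'
#' The fixed channel ordering of the 32-channel retina code:
#' frequency-major (ascending), then orientation, then sign.
#'
#' @return a data.frame with columns `channel`, `frequency`, `orientation`,
#'   `sign` (32 rows).
#' @export
filter_specs <- function() {
  fc <- .filter_constants
  g <- expand.grid(sign = fc$signs, orientation = fc$orientations,
                   frequency = fc$frequencies)
  data.frame(channel = seq_len(nrow(g)),
             frequency = g$frequency, orientation = g$orientation,
             sign = g$sign)
}

#' Build one oriented difference-of-Gaussians kernel
#'
#' @param frequency preferred spatial frequency in cycles/pixel; one of
#'   0.0625, 0.125, 0.25, 0.5.
#' @param orientation preferred orientation in degrees; one of 0, 45, 90, 135.
#' @param sign +1 or -1; the -1 kernel is the negation of the +1 kernel.
#' @return a square odd-sized numeric matrix with exactly zero DC response
#'   and unit L2 norm.
#' @details The kernel is sampled at pixel centres, the negative lobe is
#'   rescaled so the coefficients sum exactly to zero (the continuous DoG is
#'   zero-mean; sampling and truncation leave a small residual), and the
#'   result is L2-normalised.
#' @export
build_filter <- function(frequency, orientation, sign = 1) {
  fc <- .filter_constants
  if (!frequency %in% fc$frequencies)
    stop("unsupported frequency: ", frequency, call. = FALSE)
  if (!orientation %in% fc$orientations)
    stop("unsupported orientation: ", orientation, call. = FALSE)
  if (!sign %in% fc$signs)
    stop("sign must be +1 or -1", call. = FALSE)
  sc <- fc$centre_sigma(frequency)
  ss <- fc$surround_ratio * sc
  se <- fc$envelope_ratio * sc
  half <- ceiling(fc$truncation * max(se, ss))
  x <- matrix(-half:half, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  y <- matrix(-half:half, 2 * half + 1, 2 * half + 1)
  th <- orientation * pi / 180
  u <- x * cos(th) + y * sin(th)       # along preferred orientation
  v <- -x * sin(th) + y * cos(th)      # modulation axis
  k <- exp(-u^2 / (2 * se^2)) *
    (exp(-v^2 / (2 * sc^2)) / sc - exp(-v^2 / (2 * ss^2)) / ss)
  pos <- sum(k[k > 0]); neg <- -sum(k[k < 0])
  k[k < 0] <- k[k < 0] * pos / neg     # exact zero DC
  sign * k / sqrt(sum(k^2))
}

# FFT-convolution machinery: kernels are applied by zero-padded FFT
# convolution ("same" crop), with the per-(frequency, orientation) kernel
# FFTs cached per image size.
.filter_bank <- function(size) {
  .cache_get(paste0("bank", size), function() {
    fc <- .filter_constants
    pairs <- expand.grid(orientation = fc$orientations,
                         frequency = fc$frequencies)
    kernels <- Map(function(f, o) build_filter(f, o, 1),
                   pairs$frequency, pairs$orientation)
    kmax <- max(vapply(kernels, nrow, 1L))
    pad <- nextn(size + kmax - 1, c(2, 3))
    kf <- lapply(kernels, function(k) {
      kp <- matrix(0, pad, pad)
      kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
      list(fft = fft(kp), half = (nrow(k) - 1L) %/% 2L)
    })
    list(pairs = pairs, kernel_ffts = kf, pad = pad, size = size)
  })
}

.fft_convolve_same <- function(img_fft, kf, size, pad) {
  full <- Re(fft(img_fft * kf$fft, inverse = TRUE)) / (pad * pad)
  h <- kf$half
  full[h + seq_len(size), h + seq_len(size)]
}

#' Apply the V1 filter bank to an image
#'
#' Converts a grey-level stimulus into the retina code feeding layer 1: a
#' `size` x `size` x 32 array of half-wave-rectified filter responses.
#' Dark features are treated as figure (the image is mapped to
#' `1 - grey/255` before filtering), and each (frequency, orientation) pair
#' is convolved once, its positive part filling the sign +1 channel and the
#' magnitude of its negative part the sign -1 channel.  Convolution uses
#' zero padding at the image border.
#'
#' @param image an integer grey-level matrix (0..255), e.g. a
#'   [render_face()] output.
#' @param normalise if `TRUE` (default) the whole response array is scaled
#'   to unit L2 norm, so every stimulus injects the same total drive into
#'   the network.
#' @return numeric array `size` x `size` x 32 of non-negative responses with
#'   class `"retina_output"`; channel order as in [filter_specs()].
#' @export
apply_filterbank <- function(image, normalise = TRUE) {
  if (length(dim(image)) != 2L || nrow(image) != ncol(image))
    stop("image must be a square matrix", call. = FALSE)
  size <- nrow(image)
  bank <- .filter_bank(size)
  z <- 1 - unclass(image) / 255
  zp <- matrix(0, bank$pad, bank$pad)
  zp[seq_len(size), seq_len(size)] <- z
  zf <- fft(zp)
  out <- array(0, dim = c(size, size, 2L * length(bank$kernel_ffts)))
  for (p in seq_along(bank$kernel_ffts)) {
    r <- .fft_convolve_same(zf, bank$kernel_ffts[[p]], size, bank$pad)
    out[, , 2L * p - 1L] <- pmax(r, 0)
    out[, , 2L * p] <- pmax(-r, 0)
  }
  # zap FFT round-off so truly undriven locations are exactly zero
  out[out < 1e-10 * max(out)] <- 0
  # fixed per-band gain equalisation: without it the lowest-frequency band
  # carries an order of magnitude more energy and a handful of
  # low-frequency afferents dominates every neuron's drive.  The gains are
  # frozen constants (mean band L2 over the default cartoon-face ensemble)
  # rather than per-image energies: image-dependent band scaling couples
  # the disjoint identity and expression feature pathways and destroys the
  # exact invariance the stimulus design provides.
  fc <- .filter_constants
  n_or <- length(fc$orientations) * length(fc$signs)
  for (g in seq_along(fc$frequencies)) {
    ch <- (g - 1L) * n_or + seq_len(n_or)
    out[, , ch] <- out[, , ch] / fc$band_gain[g]
  }
  if (normalise) {
    nrm <- sqrt(sum(out^2))
    if (nrm > 0) out <- out / nrm
  }
  structure(out, class = c("retina_output", "array"),
            stimulus = attributes(image)[c("label", "identity", "expression")])
}

#' @export
print.retina_output <- function(x, ...) {
  cat(sprintf("<retina_output %dx%dx%d  max %.4g  active %.1f%%>\n",
              dim(x)[1], dim(x)[2], dim(x)[3], max(x), 100 * mean(x > 0)))
  invisible(x)
}
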
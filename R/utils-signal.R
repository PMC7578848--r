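# Low-level signal primitives shared by the filtering, connectivity and
# cross-frequency modules. All filtering here is zero-phase: a linear-phase
# least-squares FIR applied forward and backward ("two-way"), which squares
# the magnitude response and cancels the phase.

#' Analytic signal via the frequency domain
#'
#' @param x real numeric vector.
#' @return complex vector of the same length whose real part is `x` and whose
#'   argument is the instantaneous phase.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Linear-phase least-squares FIR band-pass design
#'
#' Designs an odd-length (type I) symmetric FIR whose amplitude response is
#' the least-squares fit to 1 on the pass band and 0 on the stop bands, with
#' don't-care transition regions of `trans` times each edge frequency. The
#' fit is solved on a dense frequency grid.
#'
#' @param order even filter order (number of taps minus one). The default is
#'   at least three cycles of the lower edge (`3 * floor(fs / fLo)`, the
#'   convention of the two-way FIR recipe this pipeline follows), raised when
#'   needed so the filter can realize the transition band and the narrower of
#'   band width and lower transition: `1.8 * fs / min(trans * fLo, fHi -
#'   fLo)`. This keeps the two-way pass-band gain within 5 percent of unity
#'   for every band in the study grids.
#' @param fLo,fHi pass-band edges (Hz).
#' @param fs sampling rate (Hz).
#' @param trans transition-band fraction of each edge frequency.
#' @return numeric vector of `order + 1` filter coefficients.
#' @export
designFirLS <- function(fLo, fHi, fs, order = NULL, trans = 0.15) {
  nyq <- fs / 2
  if (!(fLo > 0 && fLo < fHi && fHi < nyq))
    stop("band edges must satisfy 0 < fLo < fHi < Nyquist")
  if (is.null(order))
    order <- max(3L * floor(fs / fLo),
                 ceiling(1.8 * fs / min(trans * fLo, fHi - fLo)))
  order <- as.integer(order)
  if (order %% 2 == 1) order <- order + 1L
  key <- paste(fLo, fHi, fs, order, trans, sep = "|")
  if (!is.null(.firCache[[key]])) return(.firCache[[key]])
  m <- order / 2
  lo1 <- max(fLo * (1 - trans), 0)
  hi1 <- min(fHi * (1 + trans), nyq)
  # dense grid; the desired response ramps linearly across the transition
  # regions (piecewise-linear target, as in classic least-squares designs)
  ngrid <- max(16L * (m + 1L), 512L)
  f <- seq(0, nyq, length.out = ngrid)
  d <- numeric(length(f))
  d[f >= fLo & f <= fHi] <- 1
  ramp <- f > lo1 & f < fLo
  d[ramp] <- (f[ramp] - lo1) / (fLo - lo1)
  ramp <- f > fHi & f < hi1
  d[ramp] <- (hi1 - f[ramp]) / (hi1 - fHi)
  w <- 2 * pi * f / fs
  # A(w) = c0 + 2 * sum_k c_k cos(k w), taps h[m+1 +- k] = c_k
  X <- cbind(1, 2 * cos(outer(w, seq_len(m))))
  cf <- qr.solve(qr(X), d)
  b <- c(rev(cf[-1]), cf[1], cf[-1])
  .firCache[[key]] <- b
  b
}

# Memo cache for FIR designs (the same handful of bands is designed over and
# over across segments and recordings).
.firCache <- new.env(parent = emptyenv())

# Frequency response magnitude of a FIR at the given frequencies.
firResponse <- function(b, f, fs) {
  k <- seq_along(b) - 1
  vapply(f, function(fi) {
    Mod(sum(b * exp(-1i * 2 * pi * fi / fs * k)))
  }, numeric(1))
}

# Reflection-pad a vector (or each column of a matrix) by npadL samples on
# the left and npadR on the right.
.reflectPad <- function(x, npadL, npadR = npadL) {
  if (is.matrix(x)) {
    n <- nrow(x)
    npadL <- min(npadL, n - 1L)
    npadR <- min(npadR, n - 1L)
    rbind(x[(npadL + 1):2, , drop = FALSE], x,
          x[(n - 1):(n - npadR), , drop = FALSE])
  } else {
    n <- length(x)
    npadL <- min(npadL, n - 1L)
    npadR <- min(npadR, n - 1L)
    c(x[(npadL + 1):2], x, x[(n - 1):(n - npadR)])
  }
}

# Reflection-pad the columns of x by at least npad per side (rounded up so
# the padded length is 2-3-5-smooth for fast mixed-radix FFTs) and return
# the spectrum plus the bookkeeping needed to undo the padding. The padded
# spectrum can then be multiplied by several band gains without recomputing
# the forward transform.
.fftPad <- function(x, npad) {
  norig <- nrow(x)
  target <- stats::nextn(norig + 2L * min(npad, norig - 1L), c(2, 3, 5))
  padL <- min((target - norig) %/% 2, norig - 1L)
  padR <- min(target - norig - (target - norig) %/% 2, norig - 1L)
  xp <- .reflectPad(x, padL, padR)
  list(X = stats::mvfft(xp), n = nrow(xp), padL = padL, norig = norig)
}

# Hilbert step response (x1 DC/Nyquist, x2 positive, x0 negative bins).
.analyticStep <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

# Apply a two-way FIR (spectral gain |B|^2) -- and optionally the analytic
# step -- to a padded spectrum from .fftPad, returning the unpadded series.
.applyBand <- function(fp, b, analytic = TRUE) {
  n <- fp$n
  # |B|^2 at the FFT bin frequencies (forward-backward application of b);
  # Mod of the zero-padded FFT of b evaluates B on exactly this grid.
  gain <- Mod(stats::fft(c(b, rep(0, n - length(b))))) ^ 2
  if (analytic) gain <- gain * .analyticStep(n)
  z <- stats::mvfft(fp$X * gain, inverse = TRUE) / n
  z[(fp$padL + 1):(fp$padL + fp$norig), , drop = FALSE]
}

# Core zero-phase band machinery: reflection-pad columns of x, multiply the
# spectrum by |B(w)|^2 (two-way FIR) and the analytic-signal step response,
# and return the complex band-limited analytic signal. x may be a vector or
# a samples x channels matrix.
bandAnalytic <- function(x, fLo, fHi, fs, order = NULL, trans = 0.15,
                         analytic = TRUE) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  b <- designFirLS(fLo, fHi, fs, order = order, trans = trans)
  if (nrow(x) <= length(b) %/% 2 + 1)
    stop("series too short for the filter order (", length(b) - 1, ")")
  fp <- .fftPad(x, length(b))
  z <- .applyBand(fp, b, analytic = analytic)
  if (!analytic) z <- Re(z)
  if (vec) z[, 1] else z
}

# ---- synthetic-noise synthesis ----------------------------------------

# Per-bin gain vector (two-sided, Hermitian-symmetric by folded frequency)
# for the 1/f + white-floor background, scaled so the per-sample variance is
# noiseSd^2. DC gain is zero.
.backgroundGain <- function(n, fs, noiseSd) {
  fgrid <- (seq_len(n) - 1) / n * fs
  ffold <- pmin(fgrid, fs - fgrid)
  s <- 1 / pmax(ffold, 0.75) + 0.25
  s[1] <- 0
  g <- sqrt(s)
  g * noiseSd / sqrt(sum(g ^ 2) / n)
}

# Expected per-sample variance contributed by bins whose folded frequency
# lies inside [lo, hi], for a synthesis gain vector g of length n.
.gainBandPower <- function(g, n, fs, lo, hi) {
  fgrid <- (seq_len(n) - 1) / n * fs
  ffold <- pmin(fgrid, fs - fgrid)
  sum(g[ffold >= lo & ffold <= hi] ^ 2) / n
}

# Background variance in [lo, hi] for an n-sample span.
backgroundBandPower <- function(n, fs, noiseSd, lo, hi) {
  g <- .backgroundGain(n, fs, noiseSd)
  .gainBandPower(g, n, fs, lo, hi)
}

# Draw nch independent noise channels with the given per-bin gain.
# Returns an n x nch real matrix with per-sample variance sum(g^2)/n.
.synthNoise <- function(n, nch, gain) {
  w <- matrix(stats::rnorm(n * nch), n, nch)
  X <- stats::mvfft(w) * gain
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

# Draw nch independent complex analytic narrowband series with unit-ish
# amplitude structure; only the phase (Arg) is used by callers.
.synthAnalyticBand <- function(n, nch, fs, lo, hi) {
  fgrid <- (seq_len(n) - 1) / n * fs
  g <- as.numeric(fgrid >= lo & fgrid <= hi & fgrid <= fs / 2)
  if (!any(g > 0)) stop("no FFT bins inside the requested band")
  w <- matrix(stats::rnorm(n * nch), n, nch) +
    1i * matrix(stats::rnorm(n * nch), n, nch)
  stats::mvfft(stats::mvfft(w) * g, inverse = TRUE) / n
}

# ---- circular draws ----------------------------------------------------

# von Mises sampler (Best & Fisher 1979). kappa = 0 gives uniform draws;
# kappa = Inf (or very large) collapses to mu.
rVonMises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (!is.finite(kappa) || kappa > 5e4) return(rep(mu, n))
  a <- 1 + sqrt(1 + 4 * kappa ^ 2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b ^ 2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

# Interpolate a sequence of knot angles to a per-sample lag series; linear
# interpolation of the unit phasors avoids wrap-around artifacts.
.interpAngles <- function(knots, n) {
  m <- length(knots)
  if (m == 1L) return(rep(knots, n))
  at <- seq(1, m, length.out = n)
  re <- stats::approx(seq_len(m), cos(knots), xout = at)$y
  im <- stats::approx(seq_len(m), sin(knots), xout = at)$y
  atan2(im, re)
}

# Derive a reproducible 31-bit sub-seed from a master seed and indices.
.deriveSeed <- function(master, ...) {
  idx <- c(...)
  v <- as.double(master) %% 2147483647
  for (k in seq_along(idx)) {
    v <- (v * 48271 + as.double(idx[k]) * 9973 + k) %% 2147483647
  }
  as.integer(v) + 1L
}
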
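# Morlet continuous wavelet transform of mode-velocity signals.
#
# The analytic Morlet mother wavelet psi(u) = exp(i w0 u) exp(-u^2/2) is used
# without the admissibility correction term, which is negligible for
# w0 >= 5. A daughter at scale a (fs) and shift b (fs) is
# psi_{a,b}(t) = a^(-1/2) psi((t - b)/a), so its squared L2 norm is
# independent of a and |W|^2 is comparable across frequencies. The scale of
# a daughter maps to the wavenumber of its peak response:
# nu[cm^-1] = (w0 / (2 pi a)) * 33356.40952.

#' Morlet wavelet parameters
#'
#' @param fmin,fmax frequency bounds of the analysis, cm^-1
#' @param omega0 Morlet center parameter (dimensionless, >= 5 for the
#'   analytic approximation; default 6, the standard time/frequency balance,
#'   which also makes the nu = omega0/(2 pi a) scale-frequency mapping
#'   accurate)
#' @param n_scales number of scales; when NULL, derived from
#'   \code{voices_per_octave}
#' @param voices_per_octave scale-grid density (default 12)
#' @return object of class \code{wavelet_params}
#' @export
wavelet_params <- function(fmin, fmax, omega0 = 6, n_scales = NULL,
                           voices_per_octave = 12) {
  if (omega0 < 5) stop("omega0 must be >= 5 (analytic-Morlet admissibility)")
  if (!(fmin < fmax)) stop("fmin must be < fmax")
  if (fmin <= 0) stop("fmin must be > 0")
  if (is.null(n_scales))
    n_scales <- max(2L, ceiling(log2(fmax / fmin) * voices_per_octave) + 1L)
  if (n_scales < 2) stop("n_scales must be >= 2")
  structure(list(omega0 = omega0, fmin = fmin, fmax = fmax,
                 n_scales = as.integer(n_scales)),
            class = "wavelet_params")
}

#' Evaluate a Morlet daughter wavelet
#'
#' psi_{a,b}(t) = a^(-1/2) exp(i omega0 (t-b)/a) exp(-((t-b)/a)^2 / 2)
#'
#' @param a scale, fs (> 0)
#' @param b time shift, fs
#' @param t evaluation times, fs
#' @param omega0 Morlet center parameter
#' @return complex vector of wavelet values
#' @export
morlet <- function(a, b, t, omega0 = 6) {
  if (!is.numeric(a) || a <= 0) stop("scale a must be > 0")
  u <- (t - b) / a
  (1 / sqrt(a)) * exp(1i * omega0 * u) * exp(-u^2 / 2)
}

.scale_for_cm1 <- function(nu, omega0) omega0 / (2 * pi * cm1_to_cycles_fs(nu))

# symmetric-reflection index into 1..n for arbitrary integer i
.mirror_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- ((i - 1L) %% p + p) %% p   # 0 .. p-1
  ifelse(j < n, j + 1L, p - j + 1L)
}

# convolution of x with a centered complex kernel h (length 2M+1, lag m in
# -M..M stored at h[m+M+1]); the signal is symmetric-reflection padded so
# the result has length(x) samples aligned with x
.conv_reflect <- function(x, h) {
  n <- length(x)
  M <- (length(h) - 1L) %/% 2L
  xp <- x[.mirror_index(seq(1L - M, n + M), n)]
  np <- length(xp)
  nf <- stats::nextn(np + 2L * M, 2)
  # circular layout of the centered kernel: lags 0..M head, -M..-1 tail
  hh <- complex(length.out = nf)
  hh[1:(M + 1L)] <- h[(M + 1L):(2L * M + 1L)]
  if (M > 0) hh[(nf - M + 1L):nf] <- h[1:M]
  X <- stats::fft(c(xp, rep(0, nf - np)))
  y <- stats::fft(X * stats::fft(hh), inverse = TRUE) / nf
  y[(M + 1L):(M + n)]
}

#' Continuous wavelet transform of a mode-velocity signal
#'
#' Convolves the signal with Morlet daughters on a logarithmic scale grid
#' spanning \code{[fmin, fmax]} (FFT convolution with symmetric-reflection
#' padding). The returned power is the squared magnitude |W(nu, t)|^2; no
#' per-scale renormalization is applied beyond the a^(-1/2) of the daughter,
#' so intensities are comparable across frequencies in arbitrary units.
#'
#' The cone of influence marks, per time sample, the frequency below which
#' coefficients are contaminated by the signal edges: the e-folding time of
#' the Gaussian envelope is sqrt(2) a, so at distance t_edge from the
#' nearest edge all scales a > t_edge/sqrt(2) (frequencies below
#' \code{coi[t]}) are edge-affected.
#'
#' @param signal numeric vector (length >= 64), e.g. one column of
#'   \code{Qdot}
#' @param dt timestep, fs
#' @param params a [wavelet_params()]
#' @return object of class \code{spectrogram}: list with \code{times} (fs),
#'   \code{frequencies} (cm^-1, increasing), \code{power}
#'   (n_freq x n_time), \code{coi} (cm^-1 per time)
#' @export
cwt <- function(signal, dt, params) {
  if (!inherits(params, "wavelet_params")) stop("params must be wavelet_params()")
  n <- length(signal)
  if (n < 64) stop("signal too short for wavelet analysis (need >= 64 samples)")
  nyq <- cycles_fs_to_cm1(1 / (2 * dt))
  if (params$fmax > nyq)
    stop(sprintf("fmax (%g cm^-1) exceeds the Nyquist frequency %g cm^-1 for dt = %g fs",
                 params$fmax, nyq, dt))
  freqs <- exp(seq(log(params$fmin), log(params$fmax),
                   length.out = params$n_scales))
  W <- matrix(0 + 0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    a <- .scale_for_cm1(freqs[k], params$omega0)
    M <- ceiling(5 * a / dt)           # Gaussian support: 5 envelope widths
    lags <- (-M:M) * dt
    h <- morlet(a, 0, lags, params$omega0) * dt
    W[k, ] <- .conv_reflect(signal, h)
  }
  times <- (seq_len(n) - 1) * dt
  t_edge <- pmin(times, (n - 1) * dt - times)
  coi <- ifelse(t_edge > 0,
                cycles_fs_to_cm1(params$omega0 / (2 * pi * (t_edge / sqrt(2)))),
                Inf)
  structure(list(times = times, frequencies = freqs, power = Mod(W)^2,
                 coi = coi, omega0 = params$omega0),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d frequencies (%.4g-%.4g cm^-1) x %d times (0-%.4g fs)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              length(x$times), max(x$times)))
  invisible(x)
}

#' Integrated power of a spectrogram over a frequency band
#'
#' Trapezoidal integral of |W|^2 over \code{[band[1], band[2]]} cm^-1 at each
#' time sample.
#'
#' @param spec a \code{spectrogram} from [cwt()]
#' @param band numeric length-2, cm^-1; must contain at least two grid
#'   frequencies
#' @return numeric vector, one integrated power per time sample
#' @export
band_power <- function(spec, band) {
  if (length(band) != 2 || !(band[1] < band[2])) stop("band must be [lo, hi] with lo < hi")
  if (band[1] < min(spec$frequencies) || band[2] > max(spec$frequencies))
    stop("band outside the spectrogram frequency range")
  sel <- spec$frequencies >= band[1] & spec$frequencies <= band[2]
  if (sum(sel) < 2) stop("empty band: fewer than two grid frequencies inside it")
  f <- spec$frequencies[sel]
  out <- apply(spec$power[sel, , drop = FALSE], 2, function(p) pracma::trapz(f, p))
  # time after which the slowest scale in the band is clear of the left edge
  attr(out, "coi_clear_fs") <-
    sqrt(2) * .scale_for_cm1(band[1], spec$omega0)
  out
}

#' Decay time of a band-power series
#'
#' Smooths the series with a centered moving average, locates its early
#' maximum (within the first quarter of the window), and returns the elapsed
#' time from that maximum to the first sample after which the smoothed
#' power stays below \code{threshold_fraction} times the maximum. For an
#' amplitude envelope exp(-t/tau) the band power decays as exp(-2t/tau), so
#' the 1/e crossing is recovered at tau/2 after the maximum. Returns
#' \code{Inf} when the series never decays below the threshold.
#'
#' The search for the early maximum skips the first \code{t_min} fs, where
#' wavelet coefficients are edge-attenuated (inside the cone of influence);
#' when the series comes from [band_power()] its \code{"coi_clear_fs"}
#' attribute supplies \code{t_min} automatically.
#'
#' @param band_series non-negative power series (>= 8 points)
#' @param dt time between samples, fs
#' @param threshold_fraction decay threshold (default 1/e)
#' @param smooth moving-average width in samples (default 5)
#' @param t_min ignore samples before this time (fs) when locating the
#'   early maximum
#' @return decay time in fs, or \code{Inf} if the threshold is never held
#' @export
decay_time <- function(band_series, dt, threshold_fraction = exp(-1), smooth = 5,
                       t_min = NULL) {
  n <- length(band_series)
  if (n < 8) stop("series too short (need >= 8 points)")
  if (any(band_series < 0)) stop("band power must be non-negative")
  if (all(band_series == 0)) stop("all-zero band power: nothing to time")
  if (is.null(t_min))
    t_min <- if (!is.null(attr(band_series, "coi_clear_fs")))
      attr(band_series, "coi_clear_fs") else 0
  s <- as.numeric(stats::filter(band_series, rep(1 / smooth, smooth), sides = 2))
  s[is.na(s)] <- band_series[is.na(s)]   # keep the edges unsmoothed
  i0 <- min(n - 1L, 1L + ceiling(t_min / dt))
  i_hi <- max(i0 + 1L, ceiling(n / 4))
  i_max <- i0 - 1L + which.max(s[i0:i_hi])
  thr <- threshold_fraction * s[i_max]
  below <- s < thr
  # first index after the maximum from which the series stays below thr
  stays <- rev(cumprod(rev(below))) > 0
  j <- which(stays & seq_len(n) > i_max)
  if (length(j) == 0) return(Inf)
  (j[1] - i_max) * dt
}

#' Ridge of a spectrogram
#'
#' Frequency of maximum power at each time sample; samples where the ridge
#' lies below the cone of influence are set to NA.
#'
#' @param spec a \code{spectrogram}
#' @param mask_coi mask edge-affected samples (default TRUE)
#' @return numeric vector of frequencies, cm^-1
#' @export
ridge <- function(spec, mask_coi = TRUE) {
  idx <- apply(spec$power, 2, which.max)
  f <- spec$frequencies[idx]
  if (mask_coi) f[f < spec$coi] <- NA_real_
  f
}
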
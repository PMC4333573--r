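#' Zero-phase band-pass filter a session
#'
#' Applies an even-order Butterworth band-pass filter forward and backward
#' (\code{signal::filtfilt}) to every region's time series, giving zero net
#' group delay — a prerequisite for meaningful instantaneous phases.
#'
#' @param x A session record (see \code{\link{read_session_table}}).
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @param order Butterworth section order (per pass; default 2).
#' @return The session with filtered \code{samples} and a \code{band} field.
#' @export
bandpass <- function(x, low = 0.04, high = 0.07, order = 2) {
  fs <- 1 / x$sampling_period
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band [", low, ", ", high, "] Hz outside (0, Nyquist=", nyq, ") Hz")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  x$samples <- apply(x$samples, 2, function(col)
    signal::filtfilt(bf, col - mean(col)))
  x$band <- c(low, high)
  x
}

#' Instantaneous phases and amplitudes via the analytic signal
#'
#' Computes, per region, the analytic signal z(t) = a(t) + j H[a(t)] of the
#' narrowband series a(t) (H the Hilbert transform, implemented through the
#' FFT), and returns its argument (phase, wrapped to (-pi, pi]) and modulus
#' (amplitude envelope). \code{trim} frames are dropped at each border to
#' avoid the transform's edge effects (default 10, so a 300-frame session
#' retains 280).
#'
#' @param x A filtered session record (see \code{\link{bandpass}}).
#' @param trim Frames discarded at each border.
#' @return An object of class \code{phase_set}: list with \code{phases} and
#'   \code{amplitudes} (frames x regions), \code{band},
#'   \code{sampling_period}, \code{trim}, \code{flagged} (indices of
#'   degenerate all-zero regions).
#' @export
analytic_phases <- function(x, trim = 10) {
  stopifnot(trim >= 0)
  Tn <- nrow(x$samples)
  if (Tn - 2 * trim < 10) stop("too few frames after trimming")
  flagged <- which(apply(x$samples, 2, function(col) all(col == 0)))
  if (length(flagged)) {
    warning("all-zero region(s) with undefined phase: ",
            paste(flagged, collapse = ", "))
  }
  z <- apply(x$samples, 2, analytic_signal)
  keep <- (trim + 1):(Tn - trim)
  phases <- Arg(z)[keep, , drop = FALSE]
  phases[phases == -pi] <- pi
  structure(list(phases = phases,
                 amplitudes = Mod(z)[keep, , drop = FALSE],
                 band = x$band, sampling_period = x$sampling_period,
                 trim = trim, flagged = flagged,
                 region_labels = x$region_labels),
            class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat("Analytic phase set: ", nrow(x$phases), " frames x ",
      ncol(x$phases), " regions (", x$trim, " frames trimmed per border)\n",
      sep = "")
  invisible(x)
}

# FFT-based analytic signal of a real series
analytic_signal <- function(a) {
  n <- length(a)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(a) * h, inverse = TRUE) / n
}

#' Kuramoto order parameter time series
#'
#' R(t) = |sum_k exp(j phi_k(t))| / n: 0 for incoherent phases, 1 when all
#' phases coincide.
#'
#' @param p A \code{phase_set}, or a frames x regions phase matrix (radians).
#' @return Numeric vector of R values in [0, 1], one per frame.
#' @export
order_parameter <- function(p) {
  ph <- phase_matrix(p)
  stopifnot(ncol(ph) >= 2)
  Mod(rowMeans(exp(1i * ph)))
}

#' Phase-locking value matrix
#'
#' PLV(k, l) = |mean_t exp(j (phi_k(t) - phi_l(t)))|: 0 for independent
#' phases, 1 for a constant phase relation. Symmetric with unit diagonal.
#'
#' @param p A \code{phase_set} or phase matrix.
#' @return n x n PLV matrix in [0, 1].
#' @export
plv_matrix <- function(p) {
  ph <- phase_matrix(p)
  stopifnot(nrow(ph) >= 2)
  z <- exp(1i * ph)
  m <- Mod(crossprod(Conj(z), z)) / nrow(ph)   # |sum_t conj(z_k) z_l| / T
  m <- pmin(m, 1)
  diag(m) <- 1
  (m + t(m)) / 2
}

#' Probability density of pairwise phase differences
#'
#' Histogram of wrapped phase differences over all ordered region pairs,
#' pooled over frames (or one histogram per frame), normalized to sum 1.
#'
#' @param p A \code{phase_set} or phase matrix.
#' @param bins Number of equal-width bins over (-pi, pi].
#' @param per_frame If TRUE, return a frames x bins matrix of per-frame
#'   histograms.
#' @return List with \code{breaks}, \code{mids} and \code{density}
#'   (probability per bin, summing to 1; a matrix if \code{per_frame}).
#' @export
phase_difference_pdf <- function(p, bins = 60, per_frame = FALSE) {
  stopifnot(bins >= 8)
  ph <- phase_matrix(p)
  n <- ncol(ph)
  breaks <- seq(-pi, pi, length.out = bins + 1)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dmat <- wrap_pi(ph[, pairs[, 1], drop = FALSE] -
                  ph[, pairs[, 2], drop = FALSE])
  bin_of <- function(d) {
    # (-pi, pi] binning: right-closed intervals
    b <- ceiling((d + pi) / (2 * pi) * bins)
    b[b < 1] <- 1
    b
  }
  count2 <- function(d) {
    # both orderings of each unordered pair: d and -d
    tabulate(bin_of(d), bins) + tabulate(bin_of(wrap_pi(-d)), bins)
  }
  if (per_frame) {
    dens <- t(apply(dmat, 1, function(d) {
      h <- count2(d); h / sum(h)
    }))
  } else {
    h <- count2(as.vector(dmat))
    dens <- h / sum(h)
  }
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(bins + 1)]) / 2,
       density = dens)
}

#' Distribution of the number of synchronized pairs
#'
#' For each frame, counts the unordered region pairs whose wrapped absolute
#' phase difference is strictly below \code{threshold}; returns the
#' normalized histogram of that count N(t) over frames along with the count
#' series itself.
#'
#' @param p A \code{phase_set} or phase matrix.
#' @param threshold Synchronization threshold in radians (default pi/6).
#' @return List with \code{counts} (N(t) per frame), \code{levels}
#'   (0..n(n-1)/2) and \code{density} (probability per level, sums to 1).
#' @export
sync_pair_count_pdf <- function(p, threshold = pi / 6) {
  stopifnot(threshold > 0, threshold < pi)
  ph <- phase_matrix(p)
  n <- ncol(ph)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dmat <- abs(wrap_pi(ph[, pairs[, 1], drop = FALSE] -
                      ph[, pairs[, 2], drop = FALSE]))
  counts <- rowSums(dmat < threshold)
  levels <- 0:(n * (n - 1) / 2)
  dens <- tabulate(counts + 1L, length(levels))
  list(counts = counts, levels = levels, density = dens / sum(dens))
}

#' Power spectrum and peak frequency of the order parameter
#'
#' Mean-removed single-taper periodogram of the R(t) series; the peak
#' frequency is the argmax of power over positive frequencies. The global
#' synchronization level of resting-state BOLD fluctuates on an ultra-slow
#' time scale, so this peak is expected an order of magnitude below the
#' signal band.
#'
#' @param R_series Numeric vector of order-parameter values.
#' @param sampling_period Sampling period in seconds.
#' @return List with \code{freq} (Hz), \code{power}, \code{peak_frequency}.
#' @export
r_spectrum_peak <- function(R_series, sampling_period) {
  stopifnot(length(R_series) >= 64)
  if (stats::sd(R_series) == 0) stop("constant series: no spectral peak")
  sp <- stats::spec.pgram(stats::ts(R_series - mean(R_series),
                                    frequency = 1 / sampling_period),
                          taper = 0, detrend = FALSE, demean = FALSE,
                          plot = FALSE)
  list(freq = sp$freq, power = sp$spec,
       peak_frequency = sp$freq[which.max(sp$spec)])
}

#' Phase-randomized surrogate of a session
#'
#' Per region: the Fourier amplitudes are preserved exactly while the
#' Fourier phases are replaced by uniform random draws, with Hermitian
#' symmetry enforced so the inverse transform is real. This destroys all
#' cross-regional phase structure while keeping each region's power
#' spectrum, giving the null model of accidental synchronization.
#'
#' @param x A session record.
#' @param seed Integer seed.
#' @return The session with surrogate \code{samples}.
#' @export
phase_randomized_surrogate <- function(x, seed = 1) {
  rng <- local_rng(seed)
  x$samples <- apply(x$samples, 2, surrogate_series)
  x
}

surrogate_series <- function(a) {
  n <- length(a)
  xf <- stats::fft(a)
  half <- if (n %% 2 == 0) (n / 2 - 1) else ((n - 1) / 2)
  phi <- stats::runif(half, -pi, pi)
  rot <- complex(modulus = 1, argument = phi)
  xf[2:(half + 1)] <- Mod(xf[2:(half + 1)]) * rot
  xf[n:(n - half + 1)] <- Conj(xf[2:(half + 1)])
  # DC (and Nyquist, for even n) must stay real: keep their moduli, sign kept
  if (n %% 2 == 0) xf[n / 2 + 1] <- Mod(xf[n / 2 + 1]) *
      sign(Re(xf[n / 2 + 1]) + (Re(xf[n / 2 + 1]) == 0))
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Surrogate-corrected PLV matrix
#'
#' Subtracts from each off-diagonal PLV entry its expected value under
#' phase-randomized surrogates of the underlying signals (the finite-T bias
#' of the PLV estimator), floors at 0, and leaves the diagonal at 1.
#'
#' @param plv Observed PLV matrix.
#' @param x The session record the PLV was computed from (unfiltered).
#' @param n_surrogates Number of surrogate realizations (>= 10; 1000 in the
#'   reference analysis).
#' @param seed Integer seed.
#' @param band Band (Hz) used for the original analysis.
#' @param trim Border trim used for the original analysis.
#' @return Bias-corrected PLV matrix.
#' @export
plv_bias_correct <- function(plv, x, n_surrogates = 1000, seed = 1,
                             band = c(0.04, 0.07), trim = 10) {
  if (n_surrogates < 10) stop("n_surrogates must be >= 10")
  acc <- matrix(0, nrow(plv), ncol(plv))
  for (s in seq_len(n_surrogates)) {
    xs <- phase_randomized_surrogate(x, seed = seed + s - 1)
    ps <- analytic_phases(bandpass(xs, band[1], band[2]), trim = trim)
    acc <- acc + plv_matrix(ps)
  }
  corrected <- pmax(plv - acc / n_surrogates, 0)
  diag(corrected) <- 1
  corrected
}

#' Narrowband-signal and log-squared-amplitude correlation matrices
#'
#' Pearson correlations between all pairs of narrowband signals
#' (\code{r_signal}) and between the corresponding log-transformed squared
#' amplitude envelopes (\code{r_amp}); the log of A^2 renders the amplitude
#' statistics closer to normal before correlating. Amplitudes are floored at
#' machine epsilon (with a warning) where they touch zero, since log would
#' be undefined there.
#'
#' @param x A filtered session record (same band/length conventions as the
#'   phase set, trimmed to match).
#' @param p The \code{phase_set} computed from \code{x}.
#' @return List with matrices \code{r_signal} and \code{r_amp}.
#' @export
amplitude_and_signal_correlations <- function(x, p) {
  keep <- (p$trim + 1):(nrow(x$samples) - p$trim)
  sig <- x$samples[keep, , drop = FALSE]
  A <- p$amplitudes
  if (any(A <= 0)) {
    warning("zero amplitude(s) floored at machine epsilon before log")
    A <- pmax(A, .Machine$double.eps)
  }
  list(r_signal = stats::cor(sig), r_amp = stats::cor(log(A^2)))
}

#' Uncertainty reduction (normalized mutual information)
#'
#' Delta(y) = MI(r_signal, y) / H(r_signal), with entropies estimated from
#' equal-width histograms of the upper-triangle entries of the two matrices
#' treated as paired samples. Quantifies how much knowing y (e.g. PLV or
#' amplitude correlation) reduces uncertainty about the signal correlations.
#'
#' @param r_signal,y Same-shape symmetric matrices (or equal-length paired
#'   vectors).
#' @param bins Number of equal-width histogram bins (default 20).
#' @return Delta in [0, 1 + binning noise].
#' @export
uncertainty_reduction <- function(r_signal, y, bins = 20) {
  if (is.matrix(r_signal) && is.matrix(y)) {
    stopifnot(all(dim(r_signal) == dim(y)))
    ut <- upper.tri(r_signal)
    a <- r_signal[ut]; b <- y[ut]
  } else {
    stopifnot(length(r_signal) == length(y))
    a <- as.numeric(r_signal); b <- as.numeric(y)
  }
  if (stats::sd(a) == 0) stop("undefined Delta: degenerate r_signal (H = 0)")
  ia <- equal_width_bin(a, bins)
  ib <- equal_width_bin(b, bins)
  pa <- tabulate(ia, bins); pa <- pa / sum(pa)
  pb <- tabulate(ib, bins); pb <- pb / sum(pb)
  pj <- tabulate((ia - 1L) * bins + ib, bins * bins); pj <- pj / sum(pj)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (H(pa) + H(pb) - H(pj)) / H(pa)
}

equal_width_bin <- function(v, bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  i <- floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin.int(i, bins)
}

phase_matrix <- function(p) {
  if (inherits(p, "phase_set")) p$phases
  else if (is.matrix(p)) p
  else stop("expected a phase_set or a phase matrix")
}
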
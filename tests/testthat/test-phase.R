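test_that("band-pass filter passes the band and rejects out-of-band tones", {
  s <- tone_session(c(0.055, 0.25, 0.02, 0.14))
  f <- bandpass(s, 0.04, 0.07)
  keep <- 11:290   # discard 20 s borders
  # in-band tone: amplitude within 5%
  expect_equal(sd(f$samples[keep, 1]) * sqrt(2), 1, tolerance = 0.05)
  # far stopband tone: RMS < 10% of input RMS
  expect_lt(sqrt(mean(f$samples[keep, 2]^2)) /
            sqrt(mean(s$samples[, 2]^2)), 0.10)
  # one octave outside each band edge: at least 20 dB down
  for (j in 3:4) {
    att <- 20 * log10(sqrt(mean(f$samples[keep, j]^2)) /
                      sqrt(mean(s$samples[, j]^2)))
    expect_lt(att, -20)
  }
  # linearity: zero in, zero out
  z <- bandpass(make_session(matrix(0, 300, 2)), 0.04, 0.07)
  expect_true(all(z$samples == 0))
  # band must sit inside (0, Nyquist)
  expect_error(bandpass(s, 0.04, 0.3), "Nyquist")
})

test_that("analytic signal yields the phase and envelope of a tone", {
  s <- tone_session(0.05, T_frames = 300)
  f <- bandpass(s, 0.04, 0.07)
  p <- analytic_phases(f, trim = 10)
  expect_equal(nrow(p$phases), 280)   # 300 - 2 x 10
  expect_true(all(p$phases > -pi & p$phases <= pi))
  # unwrapped phase advances at 2 pi f rad/s
  dphi <- boldsync:::wrap_pi(diff(p$phases[, 1]))
  expect_equal(mean(dphi) / 2, 2 * pi * 0.05, tolerance = 0.02)
  # unit envelope away from borders
  expect_equal(mean(p$amplitudes[41:240, 1]), 1, tolerance = 0.05)

  # sine lags cosine by pi/2
  t <- (0:299) * 2
  s2 <- make_session(cbind(cos(2 * pi * 0.05 * t), sin(2 * pi * 0.05 * t)))
  p2 <- analytic_phases(bandpass(s2, 0.04, 0.07), trim = 10)
  lag <- boldsync:::wrap_pi(p2$phases[41:240, 1] - p2$phases[41:240, 2])
  expect_equal(mean(lag), pi / 2, tolerance = 0.02 * pi)

  # degenerate all-zero region is flagged
  s3 <- make_session(cbind(cos(2 * pi * 0.05 * t), 0))
  expect_warning(p3 <- analytic_phases(s3, trim = 10), "all-zero")
  expect_equal(p3$flagged, 2L)
})

test_that("order parameter matches closed-form cases and its null", {
  expect_equal(order_parameter(matrix(c(0.3, 0.3, 0.3), 1, 3)), 1)
  expect_equal(order_parameter(matrix(c(0, pi / 2, pi, 3 * pi / 2), 1, 4)),
               0, tolerance = 1e-12)
  expect_equal(order_parameter(matrix(c(0, pi / 2), 1, 2)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_true(all(order_parameter(matrix(runif(600, -pi, pi), 100, 6)) >= 0))

  # independent-phase null: n E[R^2] = 1 within 3 Monte-Carlo SE
  set.seed(42)
  n <- 8; draws <- 1e4
  R2 <- order_parameter(matrix(runif(draws * n, -pi, pi), draws, n))^2
  se <- sd(n * R2) / sqrt(draws)
  expect_lt(abs(mean(n * R2) - 1), 3 * se)
})

test_that("PLV matrix has its closed-form values and invariances", {
  tt <- seq_len(280)
  # constant phase offset: PLV = 1
  ph <- boldsync:::wrap_pi(cbind(0.3 * tt, 0.3 * tt + 1.1))
  plv <- plv_matrix(ph)
  expect_equal(plv[1, 2], 1, tolerance = 1e-12)
  expect_equal(diag(plv), c(1, 1))

  # phase difference alternating 0 and pi: PLV = 0
  ph2 <- cbind(rep(0, 280), rep(c(0, pi), 140))
  expect_equal(plv_matrix(ph2)[1, 2], 0, tolerance = 1e-12)

  # invariance under a global rotation; symmetry
  set.seed(7)
  ph3 <- matrix(runif(280 * 5, -pi, pi), 280, 5)
  p1 <- plv_matrix(ph3)
  p2 <- plv_matrix(boldsync:::wrap_pi(ph3 + 1.234))
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, t(p1))

  # independent phases: PLV at the T^{-1/2} scale
  set.seed(8)
  vals <- replicate(50, plv_matrix(matrix(runif(560, -pi, pi), 280, 2))[1, 2])
  expect_gt(mean(vals < 0.15), 0.95)
})

test_that("phase-difference histogram is a symmetric probability table", {
  # identical phases: all mass in the bin containing zero
  ph <- matrix(0.4, 50, 4)
  h <- phase_difference_pdf(ph, bins = 60)
  expect_equal(sum(h$density), 1)
  expect_equal(h$density[findInterval(0, h$breaks, left.open = TRUE)], 1)

  # pair locked at pi/2: equal mass at +pi/2 and -pi/2 bins
  ph2 <- cbind(rep(0, 50), rep(pi / 2, 50))
  h2 <- phase_difference_pdf(ph2, bins = 60)
  bplus <- findInterval(pi / 2, h2$breaks, left.open = TRUE)
  bminus <- findInterval(-pi / 2, h2$breaks, left.open = TRUE)
  expect_equal(h2$density[bplus], 0.5)
  expect_equal(h2$density[bminus], 0.5)

  # independent uniform phases: consistent with a uniform histogram
  set.seed(9)
  ph3 <- matrix(runif(280 * 20, -pi, pi), 280, 20)
  h3 <- phase_difference_pdf(ph3, bins = 30)
  counts <- h3$density * 280 * choose(20, 2) * 2
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.999, df = 29))

  expect_error(phase_difference_pdf(ph, bins = 4))
})

test_that("synchronized-pair counts follow the strict threshold rule", {
  n <- 5
  ph <- matrix(1.7, 10, n)
  sp <- sync_pair_count_pdf(ph, threshold = pi / 6)
  expect_true(all(sp$counts == n * (n - 1) / 2))
  expect_equal(sum(sp$density), 1)

  # enumerated 3-region cases
  expect_equal(sync_pair_count_pdf(matrix(c(0, pi / 5, pi), 1, 3),
                                   pi / 6)$counts, 0)
  expect_equal(sync_pair_count_pdf(matrix(c(0, 0.1, pi), 1, 3),
                                   pi / 6)$counts, 1)
  # boundary is strict: |dphi| = pi/6 exactly does not count
  expect_equal(sync_pair_count_pdf(matrix(c(0, pi / 6), 1, 2),
                                   pi / 6)$counts, 0)
})

test_that("R spectrum locates a planted slow modulation", {
  t <- (0:279) * 2
  R <- 0.3 + 0.1 * sin(2 * pi * 0.006 * t)
  sp <- r_spectrum_peak(R, 2)
  bin <- diff(sp$freq[1:2])
  expect_lt(abs(sp$peak_frequency - 0.006), bin + 1e-12)
  # doubling the duration halves the bin width
  t2 <- (0:559) * 2
  sp2 <- r_spectrum_peak(0.3 + 0.1 * sin(2 * pi * 0.006 * t2), 2)
  expect_equal(diff(sp2$freq[1:2]), bin / 2, tolerance = 1e-9)
  # white noise has no tone-like peak dominance
  set.seed(10)
  spw <- r_spectrum_peak(rnorm(280), 2)
  tone_ratio <- max(sp$power) / median(sp$power)
  noise_ratio <- max(spw$power) / median(spw$power)
  expect_lt(noise_ratio, tone_ratio)
  expect_error(r_spectrum_peak(rep(0.5, 280), 2), "constant")
})

test_that("phase-randomized surrogates preserve spectra and break coupling", {
  set.seed(11)
  x <- make_session(matrix(rnorm(300 * 4), 300, 4))
  xs <- phase_randomized_surrogate(x, seed = 21)
  for (j in 1:4) {
    expect_equal(Mod(fft(xs$samples[, j])), Mod(fft(x$samples[, j])),
                 tolerance = 1e-9)
  }
  expect_true(is.numeric(xs$samples))  # inverse transform is real

  # strongly coupled planted data has higher R than its surrogate ensemble
  g <- generate_synthetic_bold(n = 12, T_frames = 300, n_communities = 1,
                               members = list(1:12), coupling = 0.9,
                               always_on = TRUE, noise_sd = 0.1, seed = 5)
  mr <- function(s) mean(order_parameter(
    analytic_phases(bandpass(s, 0.04, 0.07), trim = 10)))
  observed <- mr(g$session)
  null <- vapply(1:100, function(i)
    mr(phase_randomized_surrogate(g$session, seed = 100 + i)), 1)
  expect_lt(t.test(null, mu = observed, alternative = "less")$p.value, 0.01)
})

test_that("surrogate bias correction zeroes independent pairs only", {
  # a locked pair must carry in-band spectral width, otherwise its
  # surrogates are themselves locked (a pure tone pair is degenerate):
  # two copies of one broadband realization are locked with PLV 1, while
  # their surrogates draw independent Fourier phases
  set.seed(12)
  shared <- rnorm(300)
  locked <- cbind(shared, shared, rnorm(300), rnorm(300))
  x <- make_session(locked)
  p <- analytic_phases(bandpass(x, 0.04, 0.07), trim = 10)
  plv <- plv_matrix(p)
  corrected <- plv_bias_correct(plv, x, n_surrogates = 25, seed = 3)
  # the surrogate bias of narrowband phases scales with the effective
  # in-band sample count (about T x bandwidth / Nyquist ~ 34 here), so the
  # locked pair loses ~0.2 to the correction while staying far above the
  # independent pair
  expect_gt(corrected[1, 2], 0.7)       # locked pair survives
  expect_lt(corrected[3, 4], 0.25)      # independent pair near zero
  expect_gt(corrected[1, 2], 3 * corrected[3, 4])
  expect_equal(unname(diag(corrected)), rep(1, 4))
  expect_true(all(corrected >= 0))
  expect_error(plv_bias_correct(plv, x, n_surrogates = 0), ">= 10")
})

test_that("signal and amplitude correlations separate sign and envelope", {
  g <- generate_synthetic_bold(n = 2, T_frames = 300, n_communities = 0,
                               noise_sd = 0.2, phase_noise_sd = 0.2,
                               seed = 13)
  x <- g$session
  x$samples <- cbind(x$samples[, 1], x$samples[, 1], -x$samples[, 1],
                     x$samples[, 2])
  x$region_labels <- paste0("R", 1:4)
  f <- bandpass(x, 0.04, 0.07)
  p <- analytic_phases(f, trim = 10)
  rr <- amplitude_and_signal_correlations(f, p)
  expect_equal(rr$r_signal[1, 2], 1, tolerance = 1e-9)
  expect_equal(rr$r_amp[1, 2], 1, tolerance = 1e-9)
  # negated copy: anti-correlated signal, identical envelope
  expect_equal(rr$r_signal[1, 3], -1, tolerance = 1e-9)
  expect_equal(rr$r_amp[1, 3], 1, tolerance = 1e-9)
  # independent region: modest correlation
  expect_lt(abs(rr$r_signal[1, 4]), 0.35)
})

test_that("uncertainty reduction matches an independent MI oracle", {
  # Delta(x, x) = 1 exactly
  set.seed(14)
  x <- rnorm(2145)
  expect_equal(uncertainty_reduction(x, x, bins = 20), 1, tolerance = 1e-12)

  # independent partner at the empirical sample size: Delta below 0.1
  expect_lt(uncertainty_reduction(x, rnorm(2145), bins = 20), 0.1)

  # brute-force joint-histogram MI oracle on correlated pairs
  rho <- 0.9
  y <- rho * x + sqrt(1 - rho^2) * rnorm(2145)
  oracle <- local({
    bx <- cut(x, seq(min(x), max(x), length.out = 21),
              include.lowest = TRUE, labels = FALSE)
    by <- cut(y, seq(min(y), max(y), length.out = 21),
              include.lowest = TRUE, labels = FALSE)
    pj <- table(bx, by) / length(x)
    px <- rowSums(pj); py <- colSums(pj)
    H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    (H(px) + H(py) - H(pj)) / H(px)
  })
  expect_equal(uncertainty_reduction(x, y, bins = 20), oracle,
               tolerance = 1e-12)

  expect_error(uncertainty_reduction(rep(1, 100), rnorm(100)), "degenerate")
})
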
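#' Estimate intrinsic regional frequencies from data
#'
#' For each region and session, band-pass filters the signal and takes the
#' peak frequency of its periodogram inside the band; per-region estimates
#' are the across-session averages. Regions whose in-band spectrum has no
#' clear tone (peak-to-median power ratio below \code{min_peak_ratio}) are
#' flagged low-confidence; all estimates are clipped into the band by
#' construction.
#'
#' @param sessions A session record or list of session records.
#' @param band Frequency band (Hz).
#' @param min_peak_ratio Peak/median in-band power ratio below which a
#'   region is flagged.
#' @return Numeric vector of per-region frequencies (Hz) with attribute
#'   \code{"low_confidence"} (logical vector).
#' @export
estimate_intrinsic_frequencies <- function(sessions, band = c(0.04, 0.07),
                                           min_peak_ratio = 4) {
  if (!is.null(sessions$samples)) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  nyq <- 1 / (2 * sessions[[1]]$sampling_period)
  if (band[2] >= nyq) stop("band outside Nyquist range")
  per_session <- lapply(sessions, function(s) {
    f <- bandpass(s, band[1], band[2])
    vapply(seq_len(ncol(f$samples)), function(j) {
      sp <- stats::spec.pgram(stats::ts(f$samples[, j],
                                        frequency = 1 / s$sampling_period),
                              taper = 0, detrend = TRUE, plot = FALSE)
      inb <- sp$freq >= band[1] & sp$freq <= band[2]
      c(sp$freq[inb][which.max(sp$spec[inb])],
        max(sp$spec[inb]) / stats::median(sp$spec[inb]))
    }, numeric(2))
  })
  n_regions <- ncol(per_session[[1]])
  pk <- rowMeans(matrix(vapply(per_session, function(m) m[1, ],
                               numeric(n_regions)), nrow = n_regions))
  ratio <- rowMeans(matrix(vapply(per_session, function(m) m[2, ],
                                  numeric(n_regions)), nrow = n_regions))
  est <- pmin(pmax(pk, band[1]), band[2])
  attr(est, "low_confidence") <- ratio < min_peak_ratio
  est
}

#' Configure a Kuramoto simulation on a connectome
#'
#' Four variants: \code{"heterogeneous"} (model 1: region-specific intrinsic
#' frequencies, deterministic), \code{"shuffled"} (model 2: as model 1 but
#' the connectome's weights are resampled i.i.d. from their own
#' distribution, destroying topology), \code{"homogeneous"} (model 3: all
#' frequencies equal to \code{omega0_hz}, deterministic),
#' \code{"homogeneous_noisy"} (model 4: homogeneous plus independent white
#' phase noise of amplitude \code{sigma}).
#'
#' Units: frequencies in Hz (omega_i = 2 pi f_i rad/s), \code{dt} in
#' seconds (default 0.01 s = 10 ms); the default run of 1.2e6 steps with a
#' 5e5-step transient simulates 12,000 s and discards the first 5,000 s.
#' \code{sigma} carries units rad/sqrt(s) (white-noise intensity of the
#' delta-correlated phase noise).
#'
#' @param connectome A \code{connectome} object.
#' @param variant One of \code{"heterogeneous"}, \code{"shuffled"},
#'   \code{"homogeneous"}, \code{"homogeneous_noisy"}.
#' @param G Global coupling gain (>= 0).
#' @param frequencies Per-region intrinsic frequencies (Hz); required for
#'   the heterogeneous variants.
#' @param omega0_hz Common frequency for the homogeneous variants.
#' @param sigma Noise amplitude (rad/sqrt(s)); only the noisy variant may
#'   set it nonzero.
#' @param dt Integration step (s).
#' @param n_steps,transient_steps Total and discarded Euler steps.
#' @param sample_period Seconds between retained phase samples (default 2,
#'   the empirical TR, so model statistics are directly comparable).
#' @param seed Integer seed (initial phases, weight shuffling, noise).
#' @return A \code{kuramoto_config} list.
#' @export
kuramoto_config <- function(connectome,
                            variant = c("heterogeneous", "shuffled",
                                        "homogeneous", "homogeneous_noisy"),
                            G = 0.2, frequencies = NULL, omega0_hz = 0.05,
                            sigma = 0, dt = 0.01, n_steps = 12e5,
                            transient_steps = 5e5, sample_period = 2,
                            seed = 1) {
  variant <- match.arg(variant)
  stopifnot(inherits(connectome, "connectome"), G >= 0, dt > 0,
            transient_steps < n_steps, sigma >= 0, sample_period >= dt)
  n <- nrow(connectome$weights)
  if (variant %in% c("homogeneous", "homogeneous_noisy")) {
    frequencies <- rep(omega0_hz, n)
  }
  if (is.null(frequencies)) {
    stop("frequencies are required for the heterogeneous variants")
  }
  stopifnot(length(frequencies) == n)
  if (sigma > 0 && variant != "homogeneous_noisy") {
    stop("sigma must be zero unless variant is 'homogeneous_noisy'")
  }
  structure(list(connectome = connectome, variant = variant, G = G,
                 frequencies = frequencies, sigma = sigma, dt = dt,
                 n_steps = n_steps, transient_steps = transient_steps,
                 sample_period = sample_period, seed = seed),
            class = "kuramoto_config")
}

#' Simulate a Kuramoto phase-oscillator network
#'
#' Integrates dphi_i/dt = omega_i + G sum_j C_ij sin(phi_j - phi_i) (plus
#' sigma-amplitude white noise for the stochastic variant) with the
#' explicit Euler scheme (Euler-Maruyama increment sigma sqrt(dt) N(0,1)
#' when noisy). Row i of the connectome collects couplings incoming to
#' oscillator i. The transient is discarded and phases are retained every
#' \code{sample_period} seconds.
#'
#' @param config A \code{kuramoto_config}.
#' @param initial_phases Optional initial phases (radians); default uniform
#'   on (-pi, pi], seeded.
#' @return An object of class \code{kuramoto_sim}: list with \code{phases}
#'   (samples x regions, wrapped to (-pi, pi]), \code{unwrapped} (same,
#'   cumulative), \code{sample_period}, \code{config}.
#' @export
simulate_kuramoto <- function(config, initial_phases = NULL) {
  stopifnot(inherits(config, "kuramoto_config"))
  rng <- local_rng(config$seed)
  W <- config$connectome$weights
  if (config$variant == "shuffled") {
    W <- shuffle_connectome_weights(config$connectome,
                                    seed = config$seed)$weights
    set.seed(as.integer(config$seed))   # reseed for phases/noise stream
  }
  n <- nrow(W)
  if (is.null(initial_phases)) {
    initial_phases <- stats::runif(n, -pi, pi)
  }
  stopifnot(length(initial_phases) == n)
  omega <- 2 * pi * config$frequencies
  sample_every <- max(1, round(config$sample_period / config$dt))
  unwrapped <- .kuramoto_integrate(W, omega, config$G, config$sigma,
                                   config$dt, config$n_steps,
                                   config$transient_steps, sample_every,
                                   initial_phases)
  structure(list(phases = wrap_pi(unwrapped), unwrapped = unwrapped,
                 sample_period = sample_every * config$dt,
                 initial_phases = initial_phases, config = config),
            class = "kuramoto_sim")
}

#' @export
print.kuramoto_sim <- function(x, ...) {
  cfg <- x$config
  cat("Kuramoto simulation (", cfg$variant, "): n = ",
      ncol(x$phases), ", G = ", cfg$G,
      if (cfg$sigma > 0) paste0(", sigma = ", cfg$sigma) else "",
      ", ", nrow(x$phases), " samples every ", x$sample_period, " s\n",
      sep = "")
  cat("mean order parameter:", signif(mean(order_parameter(x$phases)), 4),
      "\n")
  invisible(x)
}

#' @export
plot.kuramoto_sim <- function(x, ...) {
  R <- order_parameter(x$phases)
  graphics::plot(seq_along(R) * x$sample_period, R, type = "l",
                 xlab = "time (s)", ylab = "order parameter R(t)",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Phase statistics of a simulated or empirical phase matrix
#'
#' Bundles the statistics used throughout the comparison harness: mean and
#' time course of the order parameter, Pr(delta phi), Pr(N), the PLV
#' matrix, and the order-parameter spectral peak.
#'
#' @param phases Frames x regions phase matrix (or \code{phase_set} /
#'   \code{kuramoto_sim}).
#' @param sampling_period Seconds per frame (taken from the object when
#'   available).
#' @param bins Bins for the phase-difference histogram.
#' @param threshold Synchronization threshold for Pr(N).
#' @return A \code{phase_stats} list: \code{R_series}, \code{mean_R},
#'   \code{plv}, \code{pdf_dphi}, \code{pdf_N}, \code{R_spectrum},
#'   \code{R_peak_frequency}.
#' @export
phase_statistics <- function(phases, sampling_period = NULL, bins = 60,
                             threshold = pi / 6) {
  if (inherits(phases, "kuramoto_sim")) {
    sampling_period <- phases$sample_period
    phases <- phases$phases
  } else if (inherits(phases, "phase_set")) {
    sampling_period <- phases$sampling_period
    phases <- phases$phases
  }
  stopifnot(!is.null(sampling_period))
  R <- order_parameter(phases)
  spec <- if (length(R) >= 64 && stats::sd(R) > 0)
    r_spectrum_peak(R, sampling_period) else NULL
  structure(list(R_series = R, mean_R = mean(R),
                 plv = plv_matrix(phases),
                 pdf_dphi = phase_difference_pdf(phases, bins = bins),
                 pdf_N = sync_pair_count_pdf(phases, threshold = threshold),
                 R_spectrum = spec,
                 R_peak_frequency = if (is.null(spec)) NA_real_ else
                   spec$peak_frequency,
                 sampling_period = sampling_period),
            class = "phase_stats")
}

#' @export
print.phase_stats <- function(x, ...) {
  cat("Phase statistics: mean R = ", signif(x$mean_R, 4),
      ", R-peak frequency = ", signif(x$R_peak_frequency, 3), " Hz, ",
      length(x$R_series), " frames\n", sep = "")
  invisible(x)
}

#' Sweep the global coupling G
#'
#' Simulates the configured model at every G in \code{G_values} (with
#' \code{n_realizations} independent realizations for the stochastic
#' variants: fresh weight shuffles for model 2, fresh noise for model 4)
#' and computes the phase statistics of each run. Across-realization mean
#' and normal-theory 95% confidence intervals of the mean order parameter
#' are reported, and histograms are averaged across realizations.
#'
#' @param config A \code{kuramoto_config} (its \code{G} is overridden).
#' @param G_values Numeric vector of coupling values.
#' @param n_realizations Realizations per G.
#' @param seed Integer base seed.
#' @param bins,threshold Histogram settings passed to
#'   \code{\link{phase_statistics}}.
#' @return An object of class \code{g_sweep}: list of per-G records with
#'   \code{G}, \code{mean_R}, \code{ci_R}, \code{pdf_dphi}, \code{pdf_N},
#'   \code{plv} (averaged), \code{R_peak_frequency} (mean), and
#'   \code{stats} (the per-realization \code{phase_stats}).
#' @export
g_sweep <- function(config, G_values, n_realizations = 1, seed = 1,
                    bins = 60, threshold = pi / 6) {
  stopifnot(length(G_values) >= 1)
  per_g <- lapply(G_values, function(G) {
    stats_list <- lapply(seq_len(n_realizations), function(r) {
      cfg <- config
      cfg$G <- G
      cfg$seed <- seed + 1000 * r + round(1e4 * G)
      phase_statistics(simulate_kuramoto(cfg), bins = bins,
                       threshold = threshold)
    })
    mR <- vapply(stats_list, function(s) s$mean_R, 1)
    ci <- if (n_realizations > 1) {
      se <- stats::sd(mR) / sqrt(n_realizations)
      mean(mR) + c(-1, 1) * stats::qt(0.975, n_realizations - 1) * se
    } else c(NA_real_, NA_real_)
    list(G = G, mean_R = mean(mR), ci_R = ci,
         pdf_dphi = average_pdfs(lapply(stats_list, `[[`, "pdf_dphi")),
         pdf_N = average_pdfs(lapply(stats_list, `[[`, "pdf_N")),
         plv = Reduce(`+`, lapply(stats_list, `[[`, "plv")) /
           n_realizations,
         R_peak_frequency = mean(vapply(stats_list, function(s)
           s$R_peak_frequency, 1), na.rm = TRUE),
         stats = stats_list)
  })
  structure(list(G_values = G_values, results = per_g,
                 n_realizations = n_realizations,
                 variant = config$variant, seed = seed),
            class = "g_sweep")
}

#' @export
print.g_sweep <- function(x, ...) {
  cat("G sweep (", x$variant, ", ", x$n_realizations,
      " realization(s)):\n", sep = "")
  for (r in x$results) {
    cat(sprintf("  G = %-8g mean R = %.4f\n", r$G, r$mean_R))
  }
  invisible(x)
}

average_pdfs <- function(pdfs) {
  out <- pdfs[[1]]
  out$density <- Reduce(`+`, lapply(pdfs, `[[`, "density")) / length(pdfs)
  out
}
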
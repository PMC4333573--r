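#' Generate a modular synthetic connectome
#'
#' Builds a directed, weighted, zero-diagonal coupling matrix with planted
#' block-modular structure: regions are split into \code{n_modules} contiguous
#' modules; each ordered off-diagonal pair receives an edge with probability
#' \code{intra_density} (same module) or \code{inter_density} (different
#' modules); present edges get log-normal weights, echoing the heavy-tailed
#' fiber-density distributions of tractography-derived connectomes.
#'
#' @param n Number of regions.
#' @param n_modules Number of planted modules (>= 1).
#' @param intra_density,inter_density Edge probabilities in [0, 1].
#' @param weight_scale Multiplicative scale applied to all weights.
#' @param meanlog,sdlog Log-normal weight parameters.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A \code{connectome} object with attribute \code{"modules"} giving
#'   the planted module assignment.
#' @export
generate_synthetic_connectome <- function(n, n_modules, intra_density = 0.8,
                                          inter_density = 0.1,
                                          weight_scale = 1,
                                          meanlog = 0, sdlog = 1, seed = 1) {
  stopifnot(n >= 2, n_modules >= 1, n_modules <= n,
            intra_density >= 0, intra_density <= 1,
            inter_density >= 0, inter_density <= 1)
  rng <- local_rng(seed)
  modules <- sort(rep_len(seq_len(n_modules), n))
  same <- outer(modules, modules, "==")
  p <- ifelse(same, intra_density, inter_density)
  present <- matrix(stats::runif(n * n) < p, n, n)
  w <- matrix(0, n, n)
  w[present] <- stats::rlnorm(sum(present), meanlog, sdlog) * weight_scale
  diag(w) <- 0
  cm <- as_connectome(w)
  attr(cm, "modules") <- modules
  cm
}

#' Shuffle connectome weights (topology-destroying control)
#'
#' Replaces every off-diagonal entry by an independent draw (with
#' replacement) from the original off-diagonal weight distribution,
#' destroying the topology while preserving the weight distribution in
#' expectation. The diagonal stays zero.
#'
#' @param c A \code{connectome} object.
#' @param seed Integer seed.
#' @return A \code{connectome} object of the same size.
#' @export
shuffle_connectome_weights <- function(c, seed = 1) {
  stopifnot(inherits(c, "connectome"))
  rng <- local_rng(seed)
  w <- c$weights
  off <- row(w) != col(w)
  pool <- w[off]
  w[off] <- sample(pool, sum(off), replace = TRUE)
  diag(w) <- 0
  out <- as_connectome(w, region_labels = c$region_labels)
  out
}

#' Generate synthetic region-resolved BOLD signals with planted communities
#'
#' Each region oscillates at its own peak frequency inside a narrow band
#' (default 0.04-0.07 Hz, the band of interest for resting-state BOLD).
#' Planted communities are transiently synchronized: during a community's
#' active epochs, each member's phase is pulled toward a shared band-limited
#' carrier phase (advancing at the band-centre frequency), closing a
#' fraction \code{coupling} of the wrapped phase gap per frame (the pull is
#' applied after the stochastic phase increment, so full coupling locks
#' members exactly). Outside active epochs phases advance at
#' the region frequency and diffuse under per-frame phase jitter of standard
#' deviation \code{phase_noise_sd}; the jitter is what dissolves a
#' community's coherence once its epoch ends, making the planted epochs the
#' ground truth for when synchronization is present. Signals are
#' unit-amplitude cosines of these phases plus white Gaussian noise.
#'
#' Activation epochs are piecewise-constant on/off processes with
#' exponential-distributed durations (mean \code{epoch_mean_s} seconds while
#' on, \code{gap_mean_s} while off), echoing the ~12 s community activations
#' observed empirically.
#'
#' @param n Number of regions.
#' @param T_frames Number of frames.
#' @param sampling_period Sampling period (seconds).
#' @param n_communities Number of planted communities (0 for none).
#' @param members Optional list of integer vectors giving each community's
#'   member regions (each of length >= 2); defaults to disjoint contiguous
#'   blocks covering all regions.
#' @param coupling Fraction of the phase gap closed per frame during active
#'   epochs, in [0, 1]; 1 locks members exactly.
#' @param band Frequency band (Hz) from which region frequencies are drawn.
#' @param region_frequencies Optional explicit per-region frequencies (Hz).
#' @param epoch_mean_s,gap_mean_s Mean on/off epoch durations (seconds).
#' @param always_on If TRUE every community is active at every frame.
#' @param phase_noise_sd Standard deviation (radians per frame) of the
#'   phase jitter driving decoherence between epochs.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param seed Integer seed.
#' @return A list with \code{session} (a session record as from
#'   \code{\link{read_session_table}}) and \code{truth}, a list with
#'   \code{membership} (n x K 0/1 matrix), \code{activations} (T x K 0/1
#'   matrix), \code{region_frequencies} (Hz), \code{phases} (the planted
#'   phase trajectories, frames x regions).
#' @export
generate_synthetic_bold <- function(n, T_frames, sampling_period = 2,
                                    n_communities = 0, members = NULL,
                                    coupling = 0.8, band = c(0.04, 0.07),
                                    region_frequencies = NULL,
                                    epoch_mean_s = 12, gap_mean_s = 24,
                                    always_on = FALSE, phase_noise_sd = 0.8,
                                    noise_sd = 0.1, seed = 1) {
  stopifnot(n >= 1, T_frames >= 4, sampling_period > 0,
            coupling >= 0, coupling <= 1, noise_sd >= 0,
            phase_noise_sd >= 0)
  rng <- local_rng(seed)
  if (is.null(region_frequencies)) {
    region_frequencies <- stats::runif(n, band[1], band[2])
  }
  stopifnot(length(region_frequencies) == n,
            all(region_frequencies >= band[1] - 1e-12),
            all(region_frequencies <= band[2] + 1e-12))

  K <- n_communities
  if (K > 0 && is.null(members)) {
    blocks <- sort(rep_len(seq_len(K), n))
    members <- split(seq_len(n), blocks)
  }
  if (K > 0) {
    stopifnot(length(members) == K,
              all(vapply(members, length, 1L) >= 2))
  }
  membership <- matrix(0, n, K)
  for (k in seq_len(K)) membership[members[[k]], k] <- 1

  activations <- matrix(0L, T_frames, K)
  for (k in seq_len(K)) {
    activations[, k] <- if (always_on) 1L else
      sample_epochs(T_frames, sampling_period, epoch_mean_s, gap_mean_s)
  }

  dt <- sampling_period
  step <- 2 * pi * region_frequencies * dt       # free phase advance / frame
  # all assemblies ride one band-limited carrier (single frequency, fixed
  # per-community phase offsets): with a common frequency there is no
  # beating between community carriers, so fluctuations of the global order
  # parameter are attributable to the planted activations; the offsets are
  # spread over [0, pi/2] so that distinct assemblies stay outside the
  # pi/6 synchronization threshold of the tensor (separable communities)
  # while concurrent activations still add up to global coherence
  carrier_freq <- mean(band)
  offsets <- if (K > 1) seq(0, pi / 2, length.out = K) else rep(0, K)
  theta <- stats::runif(n, -pi, pi)
  psi <- stats::runif(1, -pi, pi)
  phases <- matrix(0, T_frames, n)
  for (t in seq_len(T_frames)) {
    # free advance plus phase jitter, then the community pull (so full
    # coupling pins members to the carrier phase exactly)
    theta <- theta + step
    if (phase_noise_sd > 0) {
      theta <- theta + stats::rnorm(n, sd = phase_noise_sd)
    }
    for (k in seq_len(K)) {
      if (activations[t, k] == 1L) {
        m <- members[[k]]
        theta[m] <- theta[m] + coupling * wrap_pi(psi + offsets[k] - theta[m])
      }
    }
    theta <- wrap_pi(theta)
    phases[t, ] <- theta
    psi <- wrap_pi(psi + 2 * pi * carrier_freq * dt)
  }
  samples <- cos(phases)
  if (noise_sd > 0) {
    samples <- samples + matrix(stats::rnorm(T_frames * n, sd = noise_sd),
                                T_frames, n)
  }
  labels <- paste0("R", seq_len(n))
  colnames(samples) <- labels
  list(session = list(subject = 0L, run = 0L, samples = samples,
                      sampling_period = sampling_period,
                      region_labels = labels),
       truth = list(membership = membership, activations = activations,
                    region_frequencies = region_frequencies,
                    phases = phases))
}

#' Write planted ground truth as JSON
#'
#' @param truth Ground-truth list from \code{\link{generate_synthetic_bold}}.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

# alternating on/off epochs, exponential durations, minimum 2 samples on
sample_epochs <- function(T_frames, dt, epoch_mean_s, gap_mean_s) {
  out <- integer(T_frames)
  t <- 1L
  on <- stats::runif(1) < 0.5
  while (t <= T_frames) {
    mean_s <- if (on) epoch_mean_s else gap_mean_s
    len <- max(2L, as.integer(round(stats::rexp(1, 1 / mean_s) / dt)))
    idx <- t:min(T_frames, t + len - 1L)
    out[idx] <- as.integer(on)
    t <- t + len
    on <- !on
  }
  # truncation at the end of the recording can leave a 1-frame on-run;
  # epochs must last at least 2 samples
  r <- rle(out)
  last <- length(r$values)
  if (r$values[last] == 1L && r$lengths[last] < 2L) {
    out[T_frames] <- 0L
  }
  out
}

wrap_pi <- function(x) {
  # wrap to (-pi, pi]; values already in range pass through unchanged so
  # exact threshold comparisons (e.g. |dphi| < pi/6) are not perturbed by
  # modulo round-off
  out_of_range <- x <= -pi | x > pi
  if (any(out_of_range)) {
    y <- (x[out_of_range] + pi) %% (2 * pi) - pi
    y[y == -pi] <- pi
    x[out_of_range] <- y
  }
  x
}

# every generator takes an explicit integer seed; no hidden global RNG state
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
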
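#' Kullback-Leibler divergence between binned distributions
#'
#' D_KL(g, f) = sum_{bins with g > 0} g log(g / f) in nats, with the model
#' distribution f floored at \code{eps} and renormalized so bins where f
#' vanishes contribute a large finite penalty rather than infinity.
#'
#' @param g Observed (empirical) probability vector.
#' @param f Model probability vector, same binning.
#' @param eps Floor applied to f.
#' @return Nonnegative divergence in nats; 0 iff g = f bin-wise.
#' @export
kl_divergence <- function(g, f, eps = 1e-10) {
  if (length(g) != length(f)) stop("mismatched binning")
  stopifnot(all(g >= 0), all(f >= 0))
  g <- g / sum(g)
  f <- pmax(f / sum(f), eps)
  f <- f / sum(f)
  pos <- g > 0
  sum(g[pos] * log(g[pos] / f[pos]))
}

#' Rebin a synchronized-pair-count distribution
#'
#' Maps a distribution over integer pair counts 0..n(n-1)/2 onto
#' \code{bins} equal-width bins, so model and data Pr(N) histograms share a
#' binning for KL scoring even when frame counts differ.
#'
#' @param pdf_N A \code{\link{sync_pair_count_pdf}} result.
#' @param bins Number of equal-width bins.
#' @return Probability vector of length \code{bins}.
#' @export
rebin_pair_counts <- function(pdf_N, bins = 50) {
  lev <- pdf_N$levels
  idx <- pmin(floor(lev / (max(lev) + 1) * bins) + 1L, bins)
  as.vector(tapply(pdf_N$density, factor(idx, levels = seq_len(bins)),
                   sum, default = 0))
}

#' Per-G model-data similarity profile
#'
#' Scores every G of a sweep against the empirical statistics: similarity
#' 1/D_KL for the phase-difference and synchronized-pair-count
#' distributions (capped at \code{1/eps_sim} when the distributions
#' coincide), Pearson agreement between PLV matrices with a Fisher-z 95%
#' CI, mean R of model and data, and the model's R-peak frequency. When
#' \code{normalize_to} is supplied (the profile of the reference
#' heterogeneous model), each similarity column is normalized by that
#' profile's maximum, following the convention of normalizing all
#' similarities to the best value of the reference model.
#'
#' @param data_stats A \code{phase_stats} of the empirical data.
#' @param sweep A \code{\link{g_sweep}} result.
#' @param normalize_to Optional \code{fit_report} used for normalization.
#' @param n_bins_N Equal-width bins for Pr(N) rebinning.
#' @param eps_sim Similarity cap parameter.
#' @return An object of class \code{fit_report}: data.frame with one row
#'   per G and columns \code{G}, \code{mean_R_model}, \code{mean_R_data},
#'   \code{similarity_dphi}, \code{similarity_N}, \code{plv_correlation},
#'   \code{plv_ci_lo}, \code{plv_ci_hi}, \code{R_peak_frequency_model};
#'   normalization constants kept as attributes.
#' @export
similarity_profile <- function(data_stats, sweep, normalize_to = NULL,
                               n_bins_N = 50, eps_sim = 1e-6) {
  g_dphi <- data_stats$pdf_dphi$density
  g_N <- rebin_pair_counts(data_stats$pdf_N, n_bins_N)
  rows <- lapply(sweep$results, function(r) {
    f_dphi <- r$pdf_dphi$density
    f_N <- rebin_pair_counts(r$pdf_N, n_bins_N)
    s_dphi <- 1 / max(kl_divergence(g_dphi, f_dphi), eps_sim)
    s_N <- 1 / max(kl_divergence(g_N, f_N), eps_sim)
    pa <- plv_agreement(data_stats$plv, r$plv)
    data.frame(G = r$G, mean_R_model = r$mean_R,
               mean_R_data = data_stats$mean_R,
               similarity_dphi = s_dphi, similarity_N = s_N,
               plv_correlation = pa$r, plv_ci_lo = pa$ci[1],
               plv_ci_hi = pa$ci[2],
               R_peak_frequency_model = r$R_peak_frequency)
  })
  out <- do.call(rbind, rows)
  norm_const <- if (is.null(normalize_to)) {
    c(dphi = max(out$similarity_dphi), N = max(out$similarity_N))
  } else {
    attr(normalize_to, "norm_const")
  }
  out$similarity_dphi <- out$similarity_dphi / norm_const["dphi"]
  out$similarity_N <- out$similarity_N / norm_const["N"]
  attr(out, "norm_const") <- norm_const
  attr(out, "variant") <- sweep$variant
  class(out) <- c("fit_report", "data.frame")
  out
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Model-data fit profile (", attr(x, "variant"), "):\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' Agreement between two PLV matrices
#'
#' Pearson correlation between corresponding upper-triangle entries
#' (diagonal excluded) with a Fisher z-transform 95% confidence interval on
#' the n(n-1)/2 pairs.
#'
#' @param plv_data,plv_model Same-size PLV matrices.
#' @return List with \code{r}, \code{ci} (length-2), \code{m} (pair count).
#' @export
plv_agreement <- function(plv_data, plv_model) {
  stopifnot(all(dim(plv_data) == dim(plv_model)))
  ut <- upper.tri(plv_data)
  a <- plv_data[ut]; b <- plv_model[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance PLV input: correlation undefined")
  }
  r <- stats::cor(a, b)
  m <- sum(ut)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  hw <- stats::qnorm(0.975) / sqrt(m - 3)
  list(r = r, ci = tanh(c(z - hw, z + hw)), m = m)
}

#' Model-vs-empirical community recovery across G and K
#'
#' For every coupling value: builds the model's synchronization tensor from
#' its sampled phase trajectories, factorizes it at each K, and computes
#' the largest correlation r_max between model and empirical communities
#' together with the permutation-null 95% bound (see
#' \code{\link{match_to_reference_with_null}}). The per-G probability that
#' r_max exceeds the bound across K summarizes where the model reproduces
#' the empirical community structure.
#'
#' @param trajectories_by_G Named list (names = G values) of phase matrices
#'   (frames x regions), e.g. \code{sim$phases} from
#'   \code{\link{simulate_kuramoto}} runs.
#' @param empirical_memberships n x M matrix of empirical communities.
#' @param K_range Integer vector of component counts to try.
#' @param n_permutations Permutations for the null (>= 100).
#' @param seed Integer seed.
#' @param threshold,occupancy_min Tensor construction parameters.
#' @param restarts NNTF restarts.
#' @return List with \code{table} (data.frame: G, K, r_max, r_max_perm,
#'   exceeded) and \code{exceed_probability} (named per-G fraction).
#' @export
community_recovery_curve <- function(trajectories_by_G,
                                     empirical_memberships, K_range,
                                     n_permutations = 1000, seed = 1,
                                     threshold = pi / 6,
                                     occupancy_min = 0.2, restarts = 5) {
  stopifnot(length(trajectories_by_G) >= 1, !is.null(names(trajectories_by_G)))
  rows <- list()
  for (gname in names(trajectories_by_G)) {
    tens <- build_sync_tensor(trajectories_by_G[[gname]],
                              threshold = threshold,
                              occupancy_min = occupancy_min)
    for (K in K_range) {
      d <- tryCatch(nntf(tens, K, seed = seed, restarts = restarts),
                    error = function(e) NULL)
      if (is.null(d)) {
        rows[[length(rows) + 1]] <- data.frame(
          G = as.numeric(gname), K = K, r_max = NA_real_,
          r_max_perm = NA_real_, exceeded = FALSE)
        next
      }
      m <- match_to_reference_with_null(d$memberships,
                                        empirical_memberships,
                                        n_permutations = n_permutations,
                                        seed = seed + K)
      rows[[length(rows) + 1]] <- data.frame(
        G = as.numeric(gname), K = K, r_max = m$r_max,
        r_max_perm = m$r_max_perm, exceeded = m$exceeded)
    }
  }
  tab <- do.call(rbind, rows)
  prob <- tapply(tab$exceeded, tab$G, mean)
  list(table = tab, exceed_probability = prob)
}
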
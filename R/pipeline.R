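#' Run the empirical phase-synchronization analysis
#'
#' Orchestrates the per-session pipeline — band-pass, analytic phases,
#' order parameter and PLV, synchronization tensor, NNTF community
#' detection — and the concatenated-halves robustness analysis: the
#' session tensors are concatenated per half of the dataset, each half is
#' factorized, and communities are matched between halves by maximal
#' correlation. All parameters and seeds are recorded in a manifest.
#'
#' @param sessions List of session records (see \code{\link{read_sessions}}).
#' @param band Frequency band (Hz).
#' @param threshold Synchronization threshold (radians).
#' @param occupancy_min Minimum occupancy for tensor links.
#' @param trim Border frames trimmed after the analytic transform.
#' @param K Fixed number of components, or \code{NULL} to select per
#'   session by DIFFIT over \code{K_range}.
#' @param K_range Candidate K values for DIFFIT selection.
#' @param K_halves Components for the concatenated-halves tensors; defaults
#'   to \code{K} when that is fixed, otherwise to DIFFIT selection over
#'   \code{K_range}.
#' @param restarts NNTF restarts.
#' @param bins Phase-difference histogram bins.
#' @param seed Integer seed.
#' @param output_dir Optional directory: statistics written as CSV and the
#'   manifest as JSON.
#' @return List with \code{per_session} (statistics and decompositions),
#'   \code{halves} (half-tensors' decompositions and matched-community
#'   correlations), \code{community_pool} (cross-session community
#'   correlation/clustering), \code{manifest}.
#' @export
run_empirical <- function(sessions, band = c(0.04, 0.07),
                          threshold = pi / 6, occupancy_min = 0.2,
                          trim = 10, K = NULL, K_range = 2:8,
                          K_halves = NULL, restarts = 5, bins = 60,
                          seed = 1, output_dir = NULL) {
  stopifnot(length(sessions) >= 1)
  per_session <- vector("list", length(sessions))
  tensors <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    ph <- analytic_phases(bandpass(s, band[1], band[2]), trim = trim)
    st <- phase_statistics(ph, bins = bins, threshold = threshold)
    tens <- build_sync_tensor(ph, threshold = threshold,
                              occupancy_min = occupancy_min)
    if (is.null(K)) {
      sel <- diffit_select(tens, K_range, seed = seed + i,
                           restarts = restarts)
      dec <- sel$decompositions[[match(sel$K, sort(unique(K_range)))]]
      K_i <- sel$K
    } else {
      dec <- nntf(tens, K, seed = seed + i, restarts = restarts)
      K_i <- K
    }
    cs <- community_strengths(dec, sampling_period = s$sampling_period)
    per_session[[i]] <- list(
      subject = s$subject, run = s$run, stats = st, decomposition = dec,
      K = K_i,
      S_R_correlation = stats::cor(cs$S_series, st$R_series),
      mean_activation_duration = if (length(cs$activation_durations))
        mean(cs$activation_durations) else NA_real_)
    tensors[[i]] <- tens
  }

  if (is.null(K_halves)) K_halves <- K
  halves <- NULL
  if (length(sessions) >= 2) {
    idx1 <- seq_len(ceiling(length(sessions) / 2))
    idx2 <- setdiff(seq_along(sessions), idx1)
    t1 <- concat_sync_tensors(tensors[idx1])
    t2 <- concat_sync_tensors(tensors[idx2])
    fit_half <- function(tn, off) {
      if (is.null(K_halves)) {
        sel <- diffit_select(tn, K_range, seed = seed + off,
                             restarts = restarts)
        sel$decompositions[[match(sel$K, sort(unique(K_range)))]]
      } else nntf(tn, K_halves, seed = seed + off, restarts = restarts)
    }
    d1 <- fit_half(t1, 101)
    d2 <- fit_half(t2, 202)
    rmat <- suppressWarnings(stats::cor(d1$memberships, d2$memberships))
    matched <- apply(rmat, 1, max, na.rm = TRUE)
    halves <- list(first = d1, second = d2, correlation = rmat,
                   matched_correlations = matched)
  }

  pool <- correlate_communities(lapply(per_session, function(p)
    p$decomposition$memberships))

  manifest <- list(
    band = band, threshold = threshold, occupancy_min = occupancy_min,
    trim = trim, K = K, K_range = K_range, K_halves = K_halves,
    restarts = restarts, bins = bins, seed = seed,
    n_sessions = length(sessions),
    mean_R = mean(vapply(per_session, function(p) p$stats$mean_R, 1)),
    mean_R_peak_frequency = mean(vapply(per_session, function(p)
      p$stats$R_peak_frequency, 1), na.rm = TRUE),
    selected_K = vapply(per_session, function(p) p$K, 1),
    mean_S_R_correlation = mean(vapply(per_session, function(p)
      p$S_R_correlation, 1), na.rm = TRUE),
    cophenetic = pool$cophenetic)

  out <- list(per_session = per_session, halves = halves,
              community_pool = pool, manifest = manifest)
  if (!is.null(output_dir)) write_empirical_outputs(out, output_dir)
  out
}

#' Run the model-fitting sweep
#'
#' Sweeps the global coupling for a model variant, scores every G against
#' the supplied empirical statistics, and (optionally) runs the
#' community-recovery comparison. Per-criterion argmax values are reported
#' separately — mean-R match, each distribution similarity, and PLV
#' agreement — plus the intersection of their top-quartile G sets; no
#' single combined scalar objective is imposed.
#'
#' @param connectome A \code{connectome}.
#' @param data_stats \code{phase_stats} of the empirical data.
#' @param variant Model variant (see \code{\link{kuramoto_config}}).
#' @param G_values Coupling grid.
#' @param frequencies Intrinsic frequencies (heterogeneous variants).
#' @param sigma Noise amplitude (noisy variant).
#' @param n_realizations Realizations per G.
#' @param normalize_to Optional reference \code{fit_report} (the
#'   heterogeneous model's) for similarity normalization.
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{kuramoto_config}} (e.g. \code{n_steps},
#'   \code{transient_steps}, \code{dt}, \code{sample_period}).
#' @return List with \code{report} (a \code{fit_report}), \code{sweep},
#'   \code{best_G} (per-criterion argmax), \code{top_quartile_G}
#'   (intersection), \code{manifest}.
#' @export
run_model_fit <- function(connectome, data_stats,
                          variant = "heterogeneous", G_values,
                          frequencies = NULL, sigma = 0,
                          n_realizations = 1, normalize_to = NULL,
                          seed = 1, ...) {
  if (length(G_values) == 0) stop("empty G grid")
  cfg <- kuramoto_config(connectome, variant = variant,
                         frequencies = frequencies, sigma = sigma,
                         seed = seed, ...)
  sweep <- g_sweep(cfg, G_values, n_realizations = n_realizations,
                   seed = seed)
  report <- similarity_profile(data_stats, sweep,
                               normalize_to = normalize_to)
  best_G <- c(
    mean_R = report$G[which.min(abs(report$mean_R_model -
                                    report$mean_R_data))],
    similarity_dphi = report$G[which.max(report$similarity_dphi)],
    similarity_N = report$G[which.max(report$similarity_N)],
    plv = report$G[which.max(report$plv_correlation)])
  top_q <- function(v) report$G[v >= stats::quantile(v, 0.75)]
  tq <- Reduce(intersect, list(
    top_q(-abs(report$mean_R_model - report$mean_R_data)),
    top_q(report$similarity_dphi), top_q(report$similarity_N),
    top_q(report$plv_correlation)))
  manifest <- list(variant = variant, G_values = G_values,
                   sigma = sigma, n_realizations = n_realizations,
                   seed = seed, best_G = as.list(best_G))
  list(report = report, sweep = sweep, best_G = best_G,
       top_quartile_G = tq, manifest = manifest)
}

#' Generate a synthetic multi-session study
#'
#' Convenience wrapper producing a list of synthetic sessions sharing
#' planted communities (fresh activations and noise per session), for
#' end-to-end pipeline exercises without any data download.
#'
#' @param times Number of sessions to generate.
#' @param ... Passed to \code{\link{generate_synthetic_bold}} (note that
#'   \code{n} there is the number of regions).
#' @param seed Integer base seed.
#' @return List with \code{sessions} and \code{truths} (per session).
#' @export
synthesize_study <- function(times, ..., seed = 1) {
  out <- lapply(seq_len(times), function(i) {
    g <- generate_synthetic_bold(..., seed = seed + i - 1)
    g$session$subject <- i
    g$session$run <- 1L
    g
  })
  list(sessions = lapply(out, `[[`, "session"),
       truths = lapply(out, `[[`, "truth"))
}

write_empirical_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(result$per_session, function(p)
    data.frame(subject = p$subject, run = p$run, K = p$K,
               mean_R = p$stats$mean_R,
               R_peak_frequency = p$stats$R_peak_frequency,
               S_R_correlation = p$S_R_correlation,
               mean_activation_duration = p$mean_activation_duration)))
  utils::write.csv(rows, file.path(output_dir, "session_statistics.csv"),
                   row.names = FALSE)
  for (i in seq_along(result$per_session)) {
    p <- result$per_session[[i]]
    utils::write.csv(p$decomposition$memberships,
                     file.path(output_dir,
                               sprintf("memberships_s%02d.csv", i)),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
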
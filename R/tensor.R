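#' Build the binary synchronization tensor
#'
#' For every frame t a symmetric n x n matrix Q(t) records which region
#' pairs are instantaneously synchronized: Q_ij(t) = 1 iff the wrapped
#' absolute phase difference |phi_j(t) - phi_i(t)| is strictly below
#' \code{threshold}. To eliminate accidental synchronizations, any pair
#' synchronized for less than a fraction \code{occupancy_min} of the frames
#' is zeroed across all frames (and recorded in \code{pruned_pairs}).
#'
#' @param p A \code{phase_set} or phase matrix (frames x regions).
#' @param threshold Synchronization threshold in radians (default pi/6).
#' @param occupancy_min Minimum occupancy fraction (default 0.2).
#' @return An object of class \code{sync_tensor}: list with \code{values}
#'   (n x n x T binary array, zero diagonal), \code{threshold},
#'   \code{occupancy_min}, \code{pruned_pairs} (2-column matrix),
#'   \code{sampling_period}.
#' @export
build_sync_tensor <- function(p, threshold = pi / 6, occupancy_min = 0.2) {
  stopifnot(threshold > 0, threshold < pi,
            occupancy_min >= 0, occupancy_min < 1)
  ph <- phase_matrix(p)
  sp <- if (inherits(p, "phase_set")) p$sampling_period else NA_real_
  Tn <- nrow(ph); n <- ncol(ph)
  values <- array(0L, c(n, n, Tn))
  for (t in seq_len(Tn)) {
    d <- abs(wrap_pi(outer(ph[t, ], ph[t, ], "-")))
    q <- (d < threshold) * 1L
    diag(q) <- 0L
    values[, , t] <- q
  }
  occ <- apply(values, c(1, 2), mean)
  prune <- which(upper.tri(occ) & occ < occupancy_min & occ > 0,
                 arr.ind = TRUE)
  below <- which(upper.tri(occ) & occ < occupancy_min, arr.ind = TRUE)
  for (r in seq_len(nrow(below))) {
    values[below[r, 1], below[r, 2], ] <- 0L
    values[below[r, 2], below[r, 1], ] <- 0L
  }
  structure(list(values = values, threshold = threshold,
                 occupancy_min = occupancy_min,
                 pruned_pairs = unname(below[below[, 1] < below[, 2], ,
                                             drop = FALSE]),
                 sampling_period = sp),
            class = "sync_tensor")
}

#' @export
print.sync_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("Synchronization tensor: ", d[1], "x", d[2], "x", d[3],
      " (threshold ", signif(x$threshold, 4), " rad, ",
      nrow(x$pruned_pairs), " pairs pruned at occupancy < ",
      x$occupancy_min, ")\n", sep = "")
  invisible(x)
}

#' Concatenate synchronization tensors along time
#'
#' @param ... \code{sync_tensor} objects with identical region dimension and
#'   threshold.
#' @return A \code{sync_tensor} spanning the concatenated frames.
#' @export
concat_sync_tensors <- function(...) {
  ts <- list(...)
  if (length(ts) == 1 && is.list(ts[[1]]) && !inherits(ts[[1]], "sync_tensor"))
    ts <- ts[[1]]
  stopifnot(length(ts) >= 1, all(vapply(ts, inherits, TRUE, "sync_tensor")))
  n <- dim(ts[[1]]$values)[1]
  arrs <- lapply(ts, function(z) z$values)
  values <- array(unlist(arrs), c(n, n, sum(vapply(arrs, function(a)
    dim(a)[3], 1))))
  structure(list(values = values, threshold = ts[[1]]$threshold,
                 occupancy_min = ts[[1]]$occupancy_min,
                 pruned_pairs = matrix(integer(), 0, 2),
                 sampling_period = ts[[1]]$sampling_period),
            class = "sync_tensor")
}

#' Nonnegative canonical (CP) decomposition of a synchronization tensor
#'
#' Factorizes the n x n x T tensor into K rank-one nonnegative components,
#' T ~ sum_k a_k o b_k o c_k, by alternating nonnegative least squares
#' (hierarchical ALS updates), minimizing the squared Frobenius error. The
#' spatial factors a_k carry the community structure (participation weight
#' of each region in community k) and the temporal factors c_k its
#' activation over time. Because every time slice is symmetric, the two
#' spatial factor matrices are tied: after free-factor convergence they are
#' rescaled-averaged and a few symmetry-constrained iterations are run, so
#' the returned object has a_k = b_k exactly.
#'
#' The best of \code{restarts} random initializations (by final objective)
#' is returned; the objective is non-increasing across iterations of each
#' run. The scale indeterminacy is fixed by balancing ||a_k||_2 = ||b_k||_2
#' and absorbing the remaining scale into c_k, so participation weights are
#' reported unnormalized.
#'
#' @param tensor A \code{sync_tensor} (or plain 3-d array).
#' @param K Number of components (>= 1).
#' @param seed Integer seed for the random initializations.
#' @param restarts Number of random restarts (default 10).
#' @param max_iter Maximum ALS iterations per run.
#' @param tol Relative objective-change convergence tolerance.
#' @return An object of class \code{sync_decomp}: list with
#'   \code{memberships} (n x K), \code{activations} (T x K), \code{K},
#'   \code{fit} (F = 1 - ||T - approx|| / ||T||), \code{strengths} (T x K,
#'   s_k(t) = c_k(t) sum_i a_k(i)), \code{objective}, \code{seed},
#'   \code{restarts}, \code{sampling_period}.
#' @export
nntf <- function(tensor, K, seed = 1, restarts = 10, max_iter = 200,
                 tol = 1e-6) {
  stopifnot(K >= 1, restarts >= 1)
  arr <- tensor_array(tensor)
  if (all(arr == 0)) stop("nothing to factorize: all-zero tensor")
  n <- dim(arr)[1]; Tn <- dim(arr)[3]
  unf <- tensor_unfoldings(arr)
  normT2 <- sum(arr^2)

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- cp_hals(unf, n, Tn, K, normT2, seed = seed + r - 1,
                   max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$obj < best$obj) best <- fit
  }

  A <- best$A; C <- best$C
  strengths <- sweep(C, 2, colSums(A), "*")
  F_val <- 1 - sqrt(max(best$obj, 0)) / sqrt(normT2)
  structure(list(memberships = A, activations = C, K = K, fit = F_val,
                 strengths = strengths, objective = best$obj,
                 seed = seed, restarts = restarts,
                 sampling_period = if (inherits(tensor, "sync_tensor"))
                   tensor$sampling_period else NA_real_),
            class = "sync_decomp")
}

#' @export
print.sync_decomp <- function(x, ...) {
  cat("Nonnegative CP decomposition: K = ", x$K, ", fit F = ",
      signif(x$fit, 4), " (", x$restarts, " restarts, seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' @export
summary.sync_decomp <- function(object, strength_threshold = 0.1, ...) {
  cs <- community_strengths(object, strength_threshold = strength_threshold)
  out <- list(K = object$K, fit = object$fit,
              total_participation = colSums(object$memberships),
              mean_strength = colMeans(cs$strengths),
              mean_activation_duration =
                if (length(cs$activation_durations))
                  mean(cs$activation_durations) else NA_real_,
              n_activations = length(cs$activation_durations))
  class(out) <- "summary.sync_decomp"
  out
}

#' @export
print.summary.sync_decomp <- function(x, ...) {
  cat("K =", x$K, " fit F =", signif(x$fit, 4), "\n")
  cat("total participation per community:",
      paste(signif(x$total_participation, 3), collapse = " "), "\n")
  cat("mean activation duration:", signif(x$mean_activation_duration, 4),
      "s over", x$n_activations, "activations\n")
  invisible(x)
}

#' @export
coef.sync_decomp <- function(object, ...) object$memberships

#' @export
fitted.sync_decomp <- function(object, ...) {
  A <- object$memberships; C <- object$activations
  n <- nrow(A); Tn <- nrow(C)
  arr <- array(0, c(n, n, Tn))
  for (k in seq_len(object$K)) {
    arr <- arr + outer(tcrossprod(A[, k]), C[, k])
  }
  arr
}

#' @export
plot.sync_decomp <- function(x, which = c("strengths", "activations"), ...) {
  which <- match.arg(which)
  m <- if (which == "strengths") x$strengths else x$activations
  t_axis <- seq_len(nrow(m)) *
    (if (is.finite(x$sampling_period)) x$sampling_period else 1)
  graphics::matplot(t_axis, m, type = "l", lty = 1,
                    xlab = "time (s)", ylab = which, ...)
  invisible(x)
}

#' Select the number of components by DIFFIT
#'
#' Computes the goodness-of-fit curve F(K) = 1 - ||T - approx(K)|| / ||T||
#' over a contiguous K range (each F via \code{\link{nntf}} with the stated
#' restarts) and selects the K maximizing
#' DIFIT(K) = [F(K) - F(K-1)] / F(K+1) over the interior of the range — the
#' point after which F enters a plateau. A \code{conventional = TRUE}
#' switch uses the successive-difference-ratio form
#' [F(K) - F(K-1)] / [F(K+1) - F(K)] instead.
#'
#' @param tensor A \code{sync_tensor} or 3-d array.
#' @param K_range Contiguous integer vector of candidate K (length >= 3).
#' @param seed,restarts,max_iter,tol Passed to \code{\link{nntf}}.
#' @param conventional Use the successive-difference-ratio variant.
#' @return List with \code{K} (selected), \code{F} (named fit curve),
#'   \code{difit} (named criterion values over the interior),
#'   \code{decompositions} (the fitted \code{sync_decomp} per K).
#' @export
diffit_select <- function(tensor, K_range, seed = 1, restarts = 10,
                          max_iter = 200, tol = 1e-6,
                          conventional = FALSE) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) < 3) stop("K_range must contain at least 3 values")
  if (any(diff(K_range) != 1)) stop("K_range must be contiguous")
  decomps <- lapply(K_range, function(K)
    nntf(tensor, K, seed = seed, restarts = restarts,
         max_iter = max_iter, tol = tol))
  Fv <- vapply(decomps, function(d) d$fit, 1)
  names(Fv) <- K_range
  dc <- difit_curve(Fv, K_range, conventional = conventional)
  list(K = dc$K, F = Fv, difit = dc$difit, decompositions = decomps,
       conventional = conventional)
}

# DIFFIT selection arithmetic on a precomputed F(K) curve
difit_curve <- function(Fv, K_range, conventional = FALSE) {
  interior <- 2:(length(K_range) - 1)
  difit <- if (conventional) {
    (Fv[interior] - Fv[interior - 1]) / (Fv[interior + 1] - Fv[interior])
  } else {
    (Fv[interior] - Fv[interior - 1]) / Fv[interior + 1]
  }
  names(difit) <- K_range[interior]
  if (length(difit) > 1 && all(difit == difit[1])) {
    warning("flat DIFIT curve; tie broken to smallest K")
  }
  list(K = K_range[interior][which.max(difit)], difit = difit)
}

#' Community activation strengths, total strength, and durations
#'
#' s_k(t) = c_k(t) sum_i a_k(i); S(t) = sum_k s_k(t). Activation durations
#' are the lengths (seconds) of maximal runs with s_k(t) above
#' \code{strength_threshold} (default 0.1).
#'
#' @param d A \code{sync_decomp}.
#' @param strength_threshold Activation threshold on s_k.
#' @param sampling_period Seconds per frame; defaults to the value recorded
#'   in \code{d} (1 if unknown).
#' @return List with \code{strengths} (T x K), \code{S_series} (length T),
#'   \code{activation_durations} (seconds, pooled over communities),
#'   \code{durations_by_community} (list).
#' @export
community_strengths <- function(d, strength_threshold = 0.1,
                                sampling_period = NULL) {
  if (is.null(sampling_period)) {
    sampling_period <- if (is.finite(d$sampling_period)) d$sampling_period
      else 1
  }
  strengths <- sweep(d$activations, 2, colSums(d$memberships), "*")
  S_series <- rowSums(strengths)
  durs <- lapply(seq_len(ncol(strengths)), function(k) {
    run_lengths(strengths[, k] > strength_threshold) * sampling_period
  })
  list(strengths = strengths, S_series = S_series,
       activation_durations = unlist(durs),
       durations_by_community = durs)
}

run_lengths <- function(active) {
  r <- rle(active)
  r$lengths[r$values]
}

#' Correlate communities across sessions and cluster them
#'
#' Pools membership vectors from all sessions, computes the Pearson
#' correlation between every pair, clusters on distance 1 - r with
#' average-linkage hierarchical clustering, and reports the cophenetic
#' correlation of the dendrogram (how faithfully the tree preserves the
#' original distances).
#'
#' @param memberships_list List of n x K membership matrices (shared n).
#' @return List with \code{correlation} (pooled matrix), \code{hclust},
#'   \code{cophenetic} coefficient, \code{dropped} (indices of
#'   zero-variance columns excluded from clustering).
#' @export
correlate_communities <- function(memberships_list) {
  if (is.matrix(memberships_list)) memberships_list <- list(memberships_list)
  n <- nrow(memberships_list[[1]])
  stopifnot(all(vapply(memberships_list, nrow, 1L) == n))
  M <- do.call(cbind, memberships_list)
  colnames(M) <- paste0("c", seq_len(ncol(M)))
  sds <- apply(M, 2, stats::sd)
  dropped <- unname(which(sds == 0))
  if (length(dropped)) {
    warning("zero-variance membership column(s) flagged: ",
            paste(dropped, collapse = ", "))
  }
  keep <- if (length(dropped)) M[, -dropped, drop = FALSE] else M
  r <- suppressWarnings(stats::cor(M))
  if (ncol(keep) < 3) {
    return(list(correlation = r, hclust = NULL, cophenetic = NA_real_,
                dropped = dropped))
  }
  rk <- stats::cor(keep)
  d <- stats::as.dist(1 - rk)
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cor(d, stats::cophenetic(hc))
  list(correlation = r, hclust = hc, cophenetic = coph, dropped = dropped)
}

#' Jaccard similarity between communities and reference maps
#'
#' Memberships are binarized at \code{binarize_threshold} (strictly above;
#' default 0.1, the convention used to compare participation weights with
#' binary resting-state-network maps); the Jaccard index
#' |intersection| / |union| is returned for every (community, reference)
#' pair, with 0 (and a warning) when the union is empty.
#'
#' @param memberships n x K membership matrix (nonnegative weights).
#' @param reference_maps n x M binary matrix of reference maps.
#' @param binarize_threshold Binarization threshold for memberships.
#' @return K x M matrix of Jaccard indices.
#' @export
jaccard_vs_reference <- function(memberships, reference_maps,
                                 binarize_threshold = 0.1) {
  reference_maps <- as.matrix(reference_maps)
  stopifnot(nrow(memberships) == nrow(reference_maps),
            all(reference_maps %in% c(0, 1)))
  B <- (memberships > binarize_threshold) * 1
  out <- matrix(0, ncol(B), ncol(reference_maps))
  empty_union <- FALSE
  for (k in seq_len(ncol(B))) {
    for (m in seq_len(ncol(reference_maps))) {
      u <- sum(B[, k] | reference_maps[, m])
      if (u == 0) {
        empty_union <- TRUE
        out[k, m] <- 0
      } else {
        out[k, m] <- sum(B[, k] & reference_maps[, m]) / u
      }
    }
  }
  if (empty_union) warning("empty union for some pair(s); Jaccard set to 0")
  out
}

#' Best community match against references, with a permutation null
#'
#' r_max is the largest Pearson correlation between any model community and
#' any reference community. The null distribution of the largest
#' correlation is built by randomly permuting the n elements of each
#' reference community \code{n_permutations} times; the upper 95% bound of
#' that null is returned along with whether r_max exceeds it.
#'
#' @param model_memberships n x K matrix of detected communities.
#' @param reference_memberships n x M matrix of reference communities.
#' @param n_permutations Number of permutations (>= 100; 1000 in the
#'   reference analysis).
#' @param seed Integer seed.
#' @return List with \code{r_max}, \code{r_max_perm} (upper 95% null
#'   bound), \code{exceeded} (logical), \code{null} (the permutation-null
#'   draws of the largest correlation).
#' @export
match_to_reference_with_null <- function(model_memberships,
                                         reference_memberships,
                                         n_permutations = 1000, seed = 1) {
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  A <- as.matrix(model_memberships)
  Rf <- as.matrix(reference_memberships)
  stopifnot(nrow(A) == nrow(Rf))
  rng <- local_rng(seed)
  r_max <- max(abs_safe_cor(A, Rf))
  n <- nrow(Rf)
  null <- vapply(seq_len(n_permutations), function(i) {
    Rp <- apply(Rf, 2, function(col) col[sample.int(n)])
    max(abs_safe_cor(A, Rp))
  }, 1)
  bound <- stats::quantile(null, 0.95, names = FALSE)
  list(r_max = r_max, r_max_perm = bound, exceeded = r_max > bound,
       null = null)
}

# pairwise Pearson correlations, zero-variance columns contribute -Inf
abs_safe_cor <- function(X, Y) {
  r <- suppressWarnings(stats::cor(X, Y))
  r[!is.finite(r)] <- -Inf
  r
}

# -- CP-HALS internals --------------------------------------------------------

tensor_array <- function(tensor) {
  arr <- if (inherits(tensor, "sync_tensor")) tensor$values else tensor
  stopifnot(length(dim(arr)) == 3)
  storage.mode(arr) <- "double"
  arr
}

tensor_unfoldings <- function(arr) {
  d <- dim(arr)
  u1 <- arr; dim(u1) <- c(d[1], d[2] * d[3])
  u2 <- aperm(arr, c(2, 1, 3)); dim(u2) <- c(d[2], d[1] * d[3])
  u3 <- aperm(arr, c(3, 1, 2)); dim(u3) <- c(d[3], d[1] * d[2])
  list(u1 = u1, u2 = u2, u3 = u3)
}

khatri_rao <- function(X, Y) {
  # column-wise Khatri-Rao: column k = kron(X[, k], Y[, k])
  K <- ncol(X)
  out <- matrix(0, nrow(X) * nrow(Y), K)
  for (k in seq_len(K)) out[, k] <- X[, k] %x% Y[, k]
  out
}

hals_update <- function(Fac, P, Q) {
  # one HALS pass over the columns of factor Fac: P = unfolding %*% KR,
  # Q = Hadamard product of the other factors' Gram matrices
  for (k in seq_len(ncol(Fac))) {
    qkk <- Q[k, k]
    if (qkk <= 0) qkk <- 1e-12
    upd <- Fac[, k] + (P[, k] - Fac %*% Q[, k]) / qkk
    upd[upd < 0] <- 0
    if (all(upd == 0)) upd[which.max(P[, k])] <- 1e-12   # revive dead column
    Fac[, k] <- upd
  }
  Fac
}

cp_objective <- function(normT2, A, B, C, P_C) {
  # ||T||^2 - 2 <T, approx> + ||approx||^2, with P_C the mode-3 MTTKRP
  gram <- crossprod(A) * crossprod(B) * crossprod(C)
  normT2 - 2 * sum(C * P_C) + sum(gram)
}

cp_hals <- function(unf, n, Tn, K, normT2, seed, max_iter, tol,
                    sym_iters = 20) {
  rng <- local_rng(seed)
  A <- matrix(stats::runif(n * K), n, K)
  B <- matrix(stats::runif(n * K), n, K)
  C <- matrix(stats::runif(Tn * K), Tn, K)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    A <- hals_update(A, unf$u1 %*% khatri_rao(C, B), crossprod(B) * crossprod(C))
    B <- hals_update(B, unf$u2 %*% khatri_rao(C, A), crossprod(A) * crossprod(C))
    P_C <- unf$u3 %*% khatri_rao(B, A)
    C <- hals_update(C, P_C, crossprod(A) * crossprod(B))
    obj <- cp_objective(normT2, A, B, C, unf$u3 %*% khatri_rao(B, A))
    if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(obj_prev, 1e-12))
      break
    obj_prev <- obj
  }
  # symmetrize: rescaled average of a_k and b_k, then constrained iterations
  for (k in seq_len(K)) {
    na <- sqrt(sum(A[, k]^2)); nb <- sqrt(sum(B[, k]^2))
    if (na > 0 && nb > 0) {
      avg <- (A[, k] / na + B[, k] / nb) / 2
      s <- sqrt(na * nb)
      A[, k] <- avg * s
    }
  }
  B <- A
  obj <- cp_objective(normT2, A, B, C, unf$u3 %*% khatri_rao(B, A))
  for (it in seq_len(sym_iters)) {
    C2 <- hals_update(C, unf$u3 %*% khatri_rao(B, A),
                      crossprod(A) * crossprod(B))
    GA <- hals_update(A, unf$u1 %*% khatri_rao(C2, B),
                      crossprod(B) * crossprod(C2))
    GB <- hals_update(B, unf$u2 %*% khatri_rao(C2, A),
                      crossprod(A) * crossprod(C2))
    A2 <- (GA + GB) / 2
    obj2 <- cp_objective(normT2, A2, A2, C2, unf$u3 %*% khatri_rao(A2, A2))
    if (obj2 > obj) break   # averaged symmetric step no longer descends
    A <- A2; B <- A2; C <- C2; obj <- obj2
  }
  # scale is balanced by the tie ||a_k|| = ||b_k||; remainder lives in c_k
  list(A = A, B = B, C = C, obj = obj)
}
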
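# In-code fixtures shared across the suite; everything is generated at test
# time, nothing is read from disk unless a test writes it first.

make_session <- function(samples, sampling_period = 2) {
  samples <- as.matrix(samples)
  list(subject = 1L, run = 1L, samples = samples,
       sampling_period = sampling_period,
       region_labels = paste0("R", seq_len(ncol(samples))))
}

# one cosine per region at the given frequencies (Hz), optional phase lags
tone_session <- function(freqs, T_frames = 300, sampling_period = 2,
                         lags = 0) {
  t <- (seq_len(T_frames) - 1) * sampling_period
  lags <- rep_len(lags, length(freqs))
  make_session(vapply(seq_along(freqs), function(i)
    cos(2 * pi * freqs[i] * t + lags[i]), numeric(T_frames)),
    sampling_period)
}

# literal rank-one (per component) community tensor: full block of ones
# (diagonal included) whenever the community is active
planted_block_tensor <- function(n, blocks, activations) {
  Tn <- nrow(activations)
  arr <- array(0, c(n, n, Tn))
  for (k in seq_along(blocks)) {
    for (t in which(activations[, k] == 1)) {
      arr[blocks[[k]], blocks[[k]], t] <- 1
    }
  }
  arr
}

# best |correlation| match of each planted community among recovered ones
membership_match <- function(recovered, planted) {
  r <- abs(suppressWarnings(stats::cor(recovered, planted)))
  apply(r, 2, max, na.rm = TRUE)
}
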
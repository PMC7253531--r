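# Shared fixture builders (everything generated in code; no stored data).

# Short desk-scale geometry: 20 FPS, small frame.
test_geometry <- function(duration = 60, frame_shape = c(64, 64)) {
  acquisition_geometry(fps = 20, frame_shape = frame_shape,
                       um_per_px = 4.40, roi_size_px = 7, duration = duration)
}

# Spike train with times on the frame grid (exact rendering/peeling).
grid_train <- function(times, duration, fps = 20) {
  spike_train(round(times * fps) / fps, duration)
}

# Noiseless, drift-free dF/F0 trace from on-grid spike times.
noiseless_dff <- function(times, duration, model = transient_model(),
                          fps = 20) {
  st <- grid_train(times, duration, fps)
  reconstruct(st, model, list(fps = fps, duration = duration))
}

# Brute-force burst grouping oracle: O(n^2)-style scan entirely independent
# of detect_bursts' rle-based implementation.
brute_bursts <- function(times, max_isi = 1.0) {
  n <- length(times)
  groups <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1] - times[j]) < max_isi) j <- j + 1
    if (j > i) groups[[length(groups) + 1]] <-
        c(start = times[i], end = times[j], n = j - i + 1)
    i <- j + 1
  }
  groups
}

# Greedy matcher: hits = true spikes with an inferred spike within tol_s.
match_spikes <- function(truth, inferred, tol_s) {
  used <- rep(FALSE, length(inferred))
  hits <- 0L
  for (tt in truth) {
    d <- abs(inferred - tt)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_s + 1e-9) {
      hits <- hits + 1L
      used[which.min(d)] <- TRUE
    }
  }
  list(hits = hits, false_pos = sum(!used))
}

# Screen-feature matrix for a list of normalized traces.
screen_feature_matrix <- function(traces, threshold = NULL) {
  t(vapply(traces, screen_features, numeric(5), threshold = threshold))
}
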
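## The nine per-neuron firing/bursting features and group summaries.

#' Detect bursts in a spike train
#'
#' A burst is a maximal run of at least two consecutive spikes whose
#' successive inter-spike intervals are all strictly smaller than `max_isi`
#' (default 1 s). Spikes spaced exactly `max_isi` apart do not concatenate.
#'
#' @param spikes A [spike_train()] (times must be sorted).
#' @param max_isi Concatenation bound, s.
#' @return `data.frame(start_s, end_s, n_spikes)`, zero rows if none.
#' @export
detect_bursts <- function(spikes, max_isi = 1.0) {
  t <- spikes$times
  if (is.unsorted(t)) {
    stop(errorCondition("spike times must be sorted",
                        class = c("caltrace_input_error", "error")))
  }
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0))
  if (length(t) < 2) return(empty)
  linked <- diff(t) < max_isi            # strict "smaller than"
  r <- rle(linked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  data.frame(start_s = t[starts[keep]],
             end_s = t[ends[keep] + 1L],
             n_spikes = ends[keep] - starts[keep] + 2L)
}

#' The nine firing/bursting features of one neuron
#'
#' Computes: `NS` (spike count), `FR` (firing rate, Hz = NS/duration),
#' `ISI_mean` and `ISI_sd` (over all consecutive inter-spike gaps, s), `B`
#' (burst count under the `max_isi` rule), `spikes_per_burst` (mean),
#' `ISI_in_burst` (mean intra-burst gap, s), `IBI` (mean interval between
#' consecutive burst starts, s) and `burst_length` (mean burst duration, s).
#' Features that are undefined for a train (e.g. burst statistics when
#' `B = 0`, ISI statistics when `NS < 2`) are returned as `NA`.
#'
#' @param spikes A [spike_train()].
#' @param max_isi Burst-concatenation bound, s.
#' @return One-row `data.frame` with the nine features plus `duration_s`.
#' @export
compute_features <- function(spikes, max_isi = 1.0) {
  t <- spikes$times
  ns <- length(t)
  isis <- if (ns >= 2) diff(t) else numeric(0)
  bursts <- detect_bursts(spikes, max_isi)
  b <- nrow(bursts)
  intra <- isis[isis < max_isi]
  data.frame(
    NS = ns,
    FR = ns / spikes$duration,
    ISI_mean = if (ns >= 2) mean(isis) else NA_real_,
    ISI_sd = if (ns >= 2) sd(isis) else NA_real_,
    B = b,
    spikes_per_burst = if (b) mean(bursts$n_spikes) else NA_real_,
    ISI_in_burst = if (b) mean(intra) else NA_real_,
    IBI = if (b >= 2) mean(diff(bursts$start_s)) else NA_real_,
    burst_length = if (b) mean(bursts$end_s - bursts$start_s) else NA_real_,
    duration_s = spikes$duration
  )
}

#' Feature matrix of a list of spike trains
#'
#' @param spike_list List of [spike_train()].
#' @param max_isi Burst-concatenation bound, s.
#' @param ids Optional neuron ids.
#' @return `data.frame`, one row per neuron (`neuron_id` first).
#' @export
feature_table <- function(spike_list, max_isi = 1.0, ids = NULL) {
  ids <- ids %||% paste0("roi_", seq_along(spike_list))
  out <- do.call(rbind, lapply(spike_list, compute_features, max_isi = max_isi))
  cbind(data.frame(neuron_id = ids), out)
}

feature_names <- function() {
  c("NS", "FR", "ISI_mean", "ISI_sd", "B", "spikes_per_burst",
    "ISI_in_burst", "IBI", "burst_length")
}

#' Group summary statistics
#'
#' Per-feature sample mean, sample SD (n-1 denominator), SEM (`SD/sqrt(n)`)
#' and n over a set of feature vectors; `NA` (undefined) entries are
#' excluded feature-wise.
#'
#' @param vectors `data.frame` of feature vectors (rows = neurons); only the
#'   nine standard feature columns present are summarized.
#' @return `data.frame(feature, mean, sd, sem, n)`.
#' @export
summarize_group <- function(vectors) {
  if (NROW(vectors) < 1) {
    stop(errorCondition("cannot summarize an empty group",
                        class = c("caltrace_input_error", "error")))
  }
  feats <- intersect(feature_names(), names(vectors))
  rows <- lapply(feats, function(f) {
    v <- vectors[[f]]
    v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    s <- if (n >= 2) sd(v) else NA_real_
    data.frame(feature = f, mean = m, sd = s,
               sem = if (n) s / sqrt(n) else NA_real_, n = n)
  })
  do.call(rbind, rows)
}
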
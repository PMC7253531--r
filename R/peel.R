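## Spike inference by the peeling algorithm: detect a supra-threshold calcium
## event, subtract the single-spike exponential template, repeat on the
## residual until no event remains.

#' Single-spike transient value
#'
#' `amplitude * exp(-t_rel / tau)` for `t_rel >= 0`, else 0.
#'
#' @param t_rel Time since spike onset, s (vectorized).
#' @param model A [transient_model()].
#' @return dF/F0 in %.
#' @export
single_transient <- function(t_rel, model) {
  ifelse(t_rel >= 0, model$amplitude * exp(-t_rel / model$tau), 0)
}

## Template sampled on the frame grid, truncated where it drops below 1e-8
## of its amplitude (subtraction of a rendered transient is then exact well
## below the 1e-6 % dF/F0 residual tolerance).
sampled_template <- function(model, fps, n_max) {
  m <- min(n_max, ceiling(model$tau * fps * log(1e8)) + 1L)
  single_transient((seq_len(m) - 1L) / fps, model)
}

#' Infer spikes by peeling
#'
#' Repeatedly locates the earliest calcium event in the residual with a
#' Schmitt trigger (arm above `model$threshold`, release below
#' `threshold / 2`, sustained for at least `min_duration_frames`), registers
#' a spike at the event-onset frame, subtracts the single-spike template and
#' re-scans. Terminates when no event remains; if `max_iterations` is
#' exhausted first, the partial train is returned with `converged = FALSE`
#' and a warning.
#'
#' At most one spike is registered per frame; temporal resolution is one
#' frame (no sub-frame interpolation). With `calibrate = TRUE` the template
#' amplitude is first rescaled to the median peak height of isolated
#' supra-threshold events in the trace.
#'
#' @param trace A [normalized_trace()] in % dF/F0.
#' @param model A [transient_model()]; defaults: amplitude 1%, tau 1 s,
#'   threshold 0.8%.
#' @param max_iterations Safety cap; default `10 * n_frames`.
#' @param min_duration_frames Minimum armed duration of an event, frames.
#' @param calibrate If `TRUE`, per-trace template-amplitude calibration.
#' @return List with `spikes` ([spike_train()]), `residual`
#'   ([normalized_trace()]), `converged` (logical), `model` (the template
#'   actually used).
#' @export
peel <- function(trace, model = transient_model(), max_iterations = NULL,
                 min_duration_frames = 2, calibrate = FALSE) {
  if (!inherits(trace, "normalized_trace")) {
    stop_param("`trace` must be a normalized_trace (% dF/F0)")
  }
  x <- trace$values
  n <- length(x)
  fps <- trace$fps
  max_iterations <- max_iterations %||% (10L * n)
  if (calibrate) {
    amp <- calibrate_amplitude(trace, model)
    if (is.finite(amp)) model$amplitude <- amp
  }
  tmpl <- sampled_template(model, fps, n)
  out <- .peel_core(x, model$threshold, model$threshold / 2,
                    as.integer(min_duration_frames), tmpl,
                    as.integer(max_iterations))
  if (!out$converged) {
    warning("peel: max_iterations reached; returning partial spike train")
  }
  times <- (out$onsets - 1L) / fps
  list(spikes = spike_train(times, n / fps),
       residual = normalized_trace(out$residual, trace$f0, fps),
       converged = out$converged,
       model = model)
}

## Median peak height of isolated supra-threshold events.
calibrate_amplitude <- function(trace, model) {
  iv <- high_activity_intervals(trace, model$threshold)
  if (!nrow(iv)) return(NA_real_)
  ## isolated: no other event within 3*tau before the onset
  gaps <- c(Inf, iv[-1, 1] - iv[-nrow(iv), 2])
  iso <- iv[gaps > 3 * model$tau, , drop = FALSE]
  if (!nrow(iso)) return(NA_real_)
  peaks <- apply(iso, 1, function(b) {
    i0 <- floor(b[1] * trace$fps) + 1L
    i1 <- min(length(trace$values), ceiling(b[2] * trace$fps))
    max(trace$values[i0:i1])
  })
  median(peaks)
}

#' Reconstruct a dF/F0 trace from a spike train
#'
#' Superposition of single-spike templates at the spike times, sampled at
#' the geometry's frame rate.
#'
#' @param spikes A [spike_train()].
#' @param model A [transient_model()].
#' @param geometry An [acquisition_geometry()] (`fps`, `duration`), or a
#'   plain frame rate if `duration` should come from the train.
#' @return A [normalized_trace()] (`f0` set to 100 by convention).
#' @export
reconstruct <- function(spikes, model, geometry) {
  if (is.numeric(geometry)) {
    geometry <- list(fps = geometry, duration = spikes$duration)
  }
  n <- round(geometry$fps * geometry$duration)
  v <- add_transients(numeric(n), spikes, model$amplitude, model$tau,
                      geometry$fps)
  normalized_trace(v, 100, geometry$fps)
}
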
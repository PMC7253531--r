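## Synthetic recordings: ground-truth spike trains, fluorescence traces and
## small movies with the statistical structure the downstream analysis assumes.

#' Firing-phenotype specification
#'
#' Describes one class of simulated neuron by its tonic (background) firing
#' rate and its bursting statistics. Bursts are clusters of spikes whose
#' internal inter-spike intervals are all below 1 s, the same bound the
#' feature-extraction stage uses to define a burst.
#'
#' @param name One of `"low"`, `"intermediate"`, `"high"`, `"inactive"`.
#' @param background_rate Tonic Poisson firing rate, spikes/s.
#' @param burst_rate Expected number of bursts over the whole recording.
#' @param spikes_per_burst_mean Mean spikes per burst (minimum burst size is 2).
#' @param intra_burst_isi Mean intra-burst inter-spike interval, s. Realized
#'   intra-burst intervals are drawn from an exponential truncated to
#'   `[0.1, 1)` s so that bursts respect the 1-s concatenation rule and
#'   consecutive spikes stay resolvable at 20 frames/s.
#' @param duration Recording duration, s.
#' @return An object of class `phenotype_spec`.
#' @seealso [default_phenotypes()], [simulate_spike_train()]
#' @export
phenotype_spec <- function(name, background_rate, burst_rate,
                           spikes_per_burst_mean, intra_burst_isi,
                           duration = 600) {
  name <- match.arg(name, c("low", "intermediate", "high", "inactive"))
  assert_scalar_num(background_rate, "background_rate", 0)
  assert_scalar_num(burst_rate, "burst_rate", 0)
  assert_scalar_num(spikes_per_burst_mean, "spikes_per_burst_mean", 0)
  assert_scalar_num(intra_burst_isi, "intra_burst_isi", 0)
  assert_scalar_num(duration, "duration", 0, strict = TRUE)
  if (name == "inactive" && (background_rate > 0 || burst_rate > 0)) {
    stop_param("an 'inactive' phenotype must have zero rates")
  }
  structure(
    list(name = name, background_rate = background_rate,
         burst_rate = burst_rate,
         spikes_per_burst_mean = spikes_per_burst_mean,
         intra_burst_isi = intra_burst_isi, duration = duration),
    class = "phenotype_spec"
  )
}

#' Default phenotype specifications
#'
#' The stock low/intermediate/high-firing (LF/IF/HF) phenotypes used by the
#' simulator, anchored to the burst-count and inter-burst-interval ranges
#' reported for cultured stem-cell-derived neurons over a 10-min recording:
#' HF neurons show roughly 40--60 bursts (typical IBI 10--16 s), IF neurons
#' 7--17 bursts (IBI 27--60 s) and LF neurons 1--7 bursts (IBI beyond 60 s);
#' "inactive" cells fire nothing.
#'
#' @param duration Recording duration in seconds (default 600 s = 10 min).
#'   Expected burst counts are stated per 10-min window and scale
#'   proportionally for other durations, so a phenotype's burst *rate* is
#'   intrinsic to the neuron, not to the recording length.
#' @return Named list of [phenotype_spec()] objects
#'   (`low`, `intermediate`, `high`, `inactive`).
#' @export
default_phenotypes <- function(duration = 600) {
  sc <- duration / 600
  list(
    low = phenotype_spec("low", background_rate = 0.02, burst_rate = 4 * sc,
                         spikes_per_burst_mean = 4, intra_burst_isi = 0.4,
                         duration = duration),
    intermediate = phenotype_spec("intermediate", background_rate = 0.05,
                                  burst_rate = 12 * sc,
                                  spikes_per_burst_mean = 5,
                                  intra_burst_isi = 0.35, duration = duration),
    high = phenotype_spec("high", background_rate = 0.10, burst_rate = 50 * sc,
                          spikes_per_burst_mean = 6, intra_burst_isi = 0.3,
                          duration = duration),
    inactive = phenotype_spec("inactive", 0, 0, 0, 0, duration = duration)
  )
}

#' Single-spike calcium transient model
#'
#' Parameters of the stereotyped fluorescence response to one action
#' potential: an instantaneous rise of `amplitude` percent dF/F0 followed by
#' a single-exponential decay with time constant `tau`. The same model drives
#' both the forward simulation and the peeling spike inference, which detects
#' events above `threshold`.
#'
#' @param amplitude Single-spike amplitude, % dF/F0 (default 1.0).
#' @param tau Decay time constant, s (default 1.0).
#' @param threshold Event-detection threshold, % dF/F0 (default 0.8).
#' @return An object of class `transient_model`.
#' @export
transient_model <- function(amplitude = 1.0, tau = 1.0, threshold = 0.8) {
  assert_scalar_num(amplitude, "amplitude", 0, strict = TRUE)
  assert_scalar_num(tau, "tau", 0, strict = TRUE)
  assert_scalar_num(threshold, "threshold", 0, strict = TRUE)
  structure(list(amplitude = amplitude, tau = tau, threshold = threshold),
            class = "transient_model")
}

#' Acquisition geometry
#'
#' Frame rate, frame size, pixel pitch and ROI size of a recording. Defaults
#' follow a wide-field setup imaging 960x720 px at 20 frames/s with
#' 4.40 um/px and square 7-px somatic ROIs.
#'
#' @param fps Frames per second.
#' @param frame_shape Integer vector `c(height_px, width_px)`.
#' @param um_per_px Pixel pitch, micrometres.
#' @param roi_size_px Side of the square ROI in pixels; must be odd.
#' @param duration Recording duration, s.
#' @return An object of class `acq_geometry`.
#' @export
acquisition_geometry <- function(fps = 20, frame_shape = c(720, 960),
                                 um_per_px = 4.40, roi_size_px = 7,
                                 duration = 600) {
  assert_scalar_num(fps, "fps", 0, strict = TRUE)
  if (length(frame_shape) != 2L || any(frame_shape < 1)) {
    stop_param("`frame_shape` must be two positive sizes (height, width)")
  }
  assert_scalar_num(um_per_px, "um_per_px", 0, strict = TRUE)
  assert_scalar_num(roi_size_px, "roi_size_px", 1)
  if (roi_size_px %% 2 != 1) stop_param("`roi_size_px` must be odd")
  assert_scalar_num(duration, "duration", 0, strict = TRUE)
  structure(
    list(fps = fps, frame_shape = as.integer(frame_shape),
         um_per_px = um_per_px, roi_size_px = as.integer(roi_size_px),
         duration = duration),
    class = "acq_geometry"
  )
}

#' Spike train
#'
#' Ordered spike onset times for one neuron over a recording of known
#' duration.
#'
#' @param times Numeric vector of spike times, s; sorted internally.
#' @param duration Recording duration, s.
#' @return An object of class `spike_train` with elements `times`, `duration`.
#' @export
spike_train <- function(times, duration) {
  assert_scalar_num(duration, "duration", 0, strict = TRUE)
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop_param("spike times must be finite")
  times <- sort(times)
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration)) {
    stop_param("spike times must lie in [0, duration)")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s\n",
              length(x$times), x$duration))
  invisible(x)
}

## Exponential ISI truncated to [lo, hi): inverse-CDF sampling.
rtrunc_exp <- function(n, mean, lo, hi) {
  if (n == 0L) return(numeric(0))
  u <- runif(n)
  p_lo <- 1 - exp(-lo / mean)
  p_hi <- 1 - exp(-hi / mean)
  -mean * log(1 - (p_lo + u * (p_hi - p_lo)))
}

#' Simulate a ground-truth spike train
#'
#' Draws tonic spikes from a homogeneous Poisson process at
#' `background_rate`, plus bursts whose onsets form a Poisson process with
#' `burst_rate` expected events per recording. Each burst holds
#' `2 + Poisson(spikes_per_burst_mean - 2)` spikes separated by exponential
#' intra-burst intervals truncated to `[0.1, 1)` s, so every simulated burst
#' satisfies the 1-s burst-concatenation rule used downstream.
#'
#' @param spec A [phenotype_spec()].
#' @param seed Integer seed; the same seed reproduces the train exactly.
#' @return A [spike_train()].
#' @export
simulate_spike_train <- function(spec, seed) {
  if (!inherits(spec, "phenotype_spec")) stop_param("`spec` must be a phenotype_spec")
  with_seed(seed, {
    dur <- spec$duration
    n_bg <- rpois(1, spec$background_rate * dur)
    times <- runif(n_bg, 0, dur)
    n_bursts <- rpois(1, spec$burst_rate)
    if (n_bursts > 0) {
      onsets <- runif(n_bursts, 0, dur)
      for (on in onsets) {
        n_spk <- 2 + rpois(1, max(spec$spikes_per_burst_mean - 2, 0))
        isis <- rtrunc_exp(n_spk - 1, spec$intra_burst_isi, 0.1, 1)
        times <- c(times, on + c(0, cumsum(isis)))
      }
    }
    spike_train(times[times < dur], dur)
  })
}

#' Default slow drift
#'
#' A gentle additive drift (a.u.): linear trend plus a sinusoid with a
#' period of at least 100 s, i.e. fluctuations far slower than the 25-s
#' block width of the spline drift correction, which can therefore remove
#' them.
#'
#' @param linear_per_s Slope, a.u. per second.
#' @param sin_amplitude Sinusoid amplitude, a.u.
#' @param sin_period Sinusoid period, s (>= 100).
#' @return A function of time (s) returning drift in a.u.
#' @export
default_drift <- function(linear_per_s = 0.005, sin_amplitude = 2,
                          sin_period = 300) {
  if (sin_period < 100) stop_param("`sin_period` must be >= 100 s")
  function(t) linear_per_s * t + sin_amplitude * sin(2 * pi * t / sin_period)
}

## Add a truncated single-spike template (in the given units) to `values`
## for each spike; first affected frame is the first frame at/after onset.
add_transients <- function(values, spikes, amp, tau, fps) {
  n <- length(values)
  if (!length(spikes$times)) return(values)
  ## truncate where the template falls below 1e-8 of its amplitude
  tail_frames <- ceiling(tau * fps * log(1e8)) + 1L
  tmpl_t <- (seq_len(tail_frames) - 1L) / fps
  for (tt in spikes$times) {
    k0 <- ceiling(tt * fps - 1e-9) + 1L   # first frame index with t >= tt
    if (k0 > n) next
    k1 <- min(n, k0 + tail_frames - 1L)
    off <- ((k0:k1) - 1L) / fps - tt
    values[k0:k1] <- values[k0:k1] + amp * exp(-off / tau)
  }
  values
}

#' Render a fluorescence trace from a spike train
#'
#' Forward model: `F*(t) = baseline * (1 + (amplitude/100) * sum_i
#' exp(-(t - t_i)/tau) * 1[t >= t_i]) + drift(t) + noise`, sampled at the
#' geometry's frame rate. Noise is additive white Gaussian on the raw
#' fluorescence.
#'
#' @param spikes A [spike_train()].
#' @param model A [transient_model()].
#' @param geometry An [acquisition_geometry()]; `fps` and `duration` are used.
#' @param baseline Resting fluorescence, a.u.; must be > 0.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param drift `NULL`, or a function of time (s) returning a.u.
#' @param seed Integer seed for the noise.
#' @return A `raw_trace` (see [raw_trace()]).
#' @export
render_fluorescence <- function(spikes, model, geometry, baseline = 100,
                                noise_sd = 0.125, drift = NULL, seed = 1) {
  assert_scalar_num(baseline, "baseline", 0, strict = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  n <- round(geometry$fps * geometry$duration)
  t <- (seq_len(n) - 1L) / geometry$fps
  f <- rep(baseline, n)
  f <- add_transients(f, spikes, baseline * model$amplitude / 100,
                      model$tau, geometry$fps)
  if (!is.null(drift)) f <- f + drift(t)
  if (noise_sd > 0) f <- f + with_seed(seed, rnorm(n, 0, noise_sd))
  raw_trace(f, geometry$fps)
}

## Radially peaked soma profile over an s x s ROI whose mean is exactly 1,
## so the ROI-averaged movie intensity equals the soma's rendered trace.
soma_profile <- function(s) {
  half <- (s - 1) / 2
  d2 <- outer((-half:half)^2, (-half:half)^2, `+`)
  g <- exp(-d2 / (2 * (s / 4)^2))
  dev <- g - mean(g)
  1 + 0.9 * dev / max(abs(dev))
}

#' Render a small movie of a simulated population
#'
#' Each soma is drawn as a compact radially peaked blob covering its square
#' ROI, scaled so that the ROI-averaged intensity equals the soma's rendered
#' fluorescence trace; pixels outside somata hold the baseline. Gaussian
#' noise is added per pixel.
#'
#' @param population List of entries `list(spikes = spike_train,
#'   center = c(y_px, x_px))` (0-based pixel centers).
#' @param model A [transient_model()].
#' @param geometry An [acquisition_geometry()] (use a small `frame_shape` and
#'   short `duration` for desk-scale work).
#' @param baseline Background and resting-soma fluorescence, a.u.
#' @param noise_sd Per-pixel Gaussian noise SD, a.u.
#' @param seed Integer seed.
#' @return A `movie_stack` (see [movie_stack()]).
#' @export
render_movie <- function(population, model, geometry, baseline = 100,
                         noise_sd = 0, seed = 1) {
  h <- geometry$frame_shape[1]; w <- geometry$frame_shape[2]
  s <- geometry$roi_size_px; half <- (s - 1L) %/% 2L
  n <- round(geometry$fps * geometry$duration)
  for (p in population) {
    cy <- p$center[1]; cx <- p$center[2]
    if (cy - half < 0 || cx - half < 0 || cy + half > h - 1 || cx + half > w - 1) {
      stop_param("soma center (", cy, ",", cx, ") leaves no ROI margin")
    }
  }
  frames <- array(baseline, dim = c(n, h, w))
  prof <- soma_profile(s)
  seeds <- derive_seeds(seed, length(population) + 1L)
  for (i in seq_along(population)) {
    p <- population[[i]]
    tr <- render_fluorescence(p$spikes, model, geometry, baseline = baseline,
                              noise_sd = 0, drift = NULL, seed = seeds[i])
    cy <- p$center[1]; cx <- p$center[2]
    ys <- (cy - half):(cy + half) + 1L
    xs <- (cx - half):(cx + half) + 1L
    dev <- tr$values - baseline           # per-frame deviation from rest
    for (j in seq_len(s)) {
      for (k in seq_len(s)) {
        frames[, ys[j], xs[k]] <- baseline + dev * prof[j, k]
      }
    }
  }
  if (noise_sd > 0) {
    frames <- frames + with_seed(seeds[length(seeds)],
                                 array(rnorm(length(frames), 0, noise_sd),
                                       dim = dim(frames)))
  }
  frames[frames < 0] <- 0
  movie_stack(frames, geometry)
}

#' Generate a labelled synthetic population of traces
#'
#' Simulates `n_per_class` neurons per phenotype, renders each spike train
#' into a raw fluorescence trace with the default drift and noise model, and
#' returns traces together with ground-truth class labels and spike trains.
#'
#' @param n_per_class Named integer vector or list, e.g.
#'   `c(low = 60, intermediate = 32, high = 8)`; names must be phenotype
#'   names present in `specs`.
#' @param specs Named list of [phenotype_spec()]; default [default_phenotypes()].
#' @param seed Integer master seed; per-neuron seeds are derived from it.
#' @param model A [transient_model()].
#' @param geometry An [acquisition_geometry()].
#' @param baseline,noise_sd,drift Passed to [render_fluorescence()];
#'   `drift = NULL` uses [default_drift()].
#' @return List with elements `traces` (list of `raw_trace`), `labels`
#'   (character vector), `spikes` (list of `spike_train`), `seed`.
#' @export
make_population <- function(n_per_class, specs = NULL, seed = 1,
                            model = transient_model(),
                            geometry = acquisition_geometry(),
                            baseline = 100, noise_sd = 0.125, drift = NULL) {
  specs <- specs %||% default_phenotypes(duration = geometry$duration)
  n_per_class <- unlist(n_per_class)
  if (is.null(names(n_per_class)) && length(n_per_class) > 0) {
    stop_param("`n_per_class` must be named by phenotype")
  }
  unknown <- setdiff(names(n_per_class), names(specs))
  if (length(unknown)) stop_param("unknown phenotype label: ", unknown[1])
  if (any(n_per_class < 0)) stop_param("counts must be >= 0")
  labels <- rep(names(n_per_class), times = n_per_class)
  n <- length(labels)
  drift <- drift %||% default_drift()
  seeds <- derive_seeds(seed, 2L * n)
  spikes <- vector("list", n); traces <- vector("list", n)
  for (i in seq_len(n)) {
    spikes[[i]] <- simulate_spike_train(specs[[labels[i]]], seeds[i])
    traces[[i]] <- render_fluorescence(spikes[[i]], model, geometry,
                                       baseline = baseline,
                                       noise_sd = noise_sd, drift = drift,
                                       seed = seeds[n + i])
  }
  list(traces = traces, labels = labels, spikes = spikes, seed = seed)
}
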
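## ROI detection, trace extraction, smoothing, drift correction and dF/F0
## normalization.

#' Raw fluorescence trace
#'
#' Per-frame ROI-averaged fluorescence, F*(t), in arbitrary camera units.
#'
#' @param values Numeric vector of fluorescence values, one per frame.
#' @param fps Frames per second.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(values, fps) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values))) {
    stop_param("trace values must be finite and non-empty")
  }
  assert_scalar_num(fps, "fps", 0, strict = TRUE)
  structure(list(values = values, fps = fps), class = "raw_trace")
}

#' Normalized trace (dF/F0, %)
#'
#' @param values Numeric vector of dF/F0 values in percent.
#' @param f0 Baseline fluorescence, a.u.; must be > 0.
#' @param fps Frames per second.
#' @return An object of class `normalized_trace`.
#' @export
normalized_trace <- function(values, f0, fps) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values))) {
    stop_param("trace values must be finite and non-empty")
  }
  assert_scalar_num(f0, "f0", 0, strict = TRUE)
  assert_scalar_num(fps, "fps", 0, strict = TRUE)
  structure(list(values = values, f0 = f0, fps = fps),
            class = "normalized_trace")
}

#' Movie stack
#'
#' A single-channel fluorescence image sequence with its acquisition
#' geometry. Frames are stored as a numeric array `(time, y, x)`.
#'
#' @param frames 3-D array `(time, y, x)` of non-negative intensities.
#' @param geometry An [acquisition_geometry()].
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, geometry) {
  if (length(dim(frames)) != 3L) stop_param("`frames` must be a 3-D array")
  if (min(frames) < 0) stop_param("intensities must be non-negative")
  structure(list(frames = frames, geometry = geometry), class = "movie_stack")
}

#' ROI set
#'
#' Square regions of interest centred on somata, 0-based `(y, x)` pixel
#' coordinates. An ROI of size `s` centred at `c` covers pixels
#' `c - (s-1)/2 ... c + (s-1)/2` inclusive.
#'
#' @param centers Two-column matrix (or data.frame) of `(y, x)` centers.
#' @param size_px Odd square side in pixels.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(centers, size_px = 7) {
  centers <- as.matrix(centers)
  if (length(centers) == 0) centers <- matrix(numeric(0), ncol = 2)
  if (ncol(centers) != 2L) stop_param("`centers` must have two columns (y, x)")
  if (size_px %% 2 != 1 || size_px < 1) stop_param("`size_px` must be odd and >= 1")
  colnames(centers) <- c("y", "x")
  structure(list(centers = centers, size_px = as.integer(size_px)),
            class = "roi_set")
}

#' Time-projected brightness image of a movie
#'
#' @param movie A [movie_stack()].
#' @param method `"mean"` (default) or `"max"` projection over time.
#' @return 2-D matrix `(y, x)`.
#' @export
brightness_image <- function(movie, method = c("mean", "max")) {
  method <- match.arg(method)
  f <- movie$frames
  if (method == "mean") apply(f, c(2, 3), mean) else apply(f, c(2, 3), max)
}

#' Detect somatic ROIs from a brightness image
#'
#' Somata are taken as local brightness maxima (8-neighbourhood) above
#' `intensity_threshold`, accepted greedily in order of decreasing brightness
#' subject to a minimum pairwise centre separation; candidates whose square
#' ROI would leave the frame are discarded. Exact brightness ties are broken
#' in row-major pixel order, making the result deterministic.
#'
#' @param brightness_image 2-D matrix of non-negative finite intensities.
#' @param size_px ROI square side (odd), default 7.
#' @param intensity_threshold Minimum brightness of an accepted maximum.
#' @param min_separation_px Minimum Euclidean distance between ROI centers.
#' @return An [roi_set()] (possibly empty).
#' @export
detect_rois <- function(brightness_image, size_px = 7, intensity_threshold,
                        min_separation_px = size_px) {
  img <- as.matrix(brightness_image)
  if (any(!is.finite(img)) || min(img) < 0) {
    stop_param("brightness image must be finite and non-negative")
  }
  h <- nrow(img); w <- ncol(img); half <- (size_px - 1L) %/% 2L
  cand <- which(img > intensity_threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1]; x <- cand[i, 2]
    if (y - 1 < half || x - 1 < half || y > h - half || x > w - half) next
    nb <- img[max(1, y - 1):min(h, y + 1), max(1, x - 1):min(w, x + 1)]
    keep[i] <- img[y, x] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(roi_set(matrix(numeric(0), ncol = 2), size_px))
  b <- img[cand]
  ord <- order(-b, cand[, 1], cand[, 2])      # brightness desc, row-major ties
  cand <- cand[ord, , drop = FALSE]
  acc <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0 ||
        all(sqrt((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= min_separation_px)) {
      acc <- rbind(acc, p)
    }
  }
  roi_set(acc - 1, size_px)                   # to 0-based coordinates
}

#' Extract ROI-averaged traces from a movie
#'
#' The trace value at frame `t` is the arithmetic mean of the ROI's pixels
#' at `t`.
#'
#' @param movie A [movie_stack()].
#' @param rois An [roi_set()]; every ROI must lie fully inside the frame.
#' @return List of [raw_trace()], one per ROI.
#' @export
extract_traces <- function(movie, rois) {
  f <- movie$frames
  h <- dim(f)[2]; w <- dim(f)[3]
  half <- (rois$size_px - 1L) %/% 2L
  fps <- movie$geometry$fps
  lapply(seq_len(nrow(rois$centers)), function(i) {
    cy <- rois$centers[i, 1]; cx <- rois$centers[i, 2]
    if (cy - half < 0 || cx - half < 0 || cy + half > h - 1 || cx + half > w - 1) {
      stop_param("ROI ", i, " extends outside the frame")
    }
    ys <- (cy - half):(cy + half) + 1L
    xs <- (cx - half):(cx + half) + 1L
    raw_trace(apply(f[, ys, xs, drop = FALSE], 1, mean), fps)
  })
}

#' Moving-average smoothing
#'
#' Centred moving average, default 5 frames (250 ms at 20 frames/s). At the
#' trace edges the window shrinks symmetrically, so no values are fabricated
#' and the length is preserved.
#'
#' @param trace A [raw_trace()] or [normalized_trace()].
#' @param window_frames Odd window width in frames, >= 1 and <= length.
#' @return Trace of the same class, smoothed.
#' @export
smooth_trace <- function(trace, window_frames = 5) {
  x <- trace$values; n <- length(x)
  if (window_frames %% 2 != 1 || window_frames < 1 || window_frames > n) {
    stop_param("`window_frames` must be odd, >= 1 and <= trace length")
  }
  half <- (window_frames - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  hw <- pmin(half, i - 1L, n - i)             # shrunken symmetric half-width
  out <- (cs[i + hw + 1L] - cs[i - hw]) / (2 * hw + 1)
  trace$values <- out
  trace
}

#' Block-spline drift correction
#'
#' Removes slow drift by subtracting a smoothed spline of the signal: the
#' trace is divided into blocks `block_s` seconds wide, the mean of each
#' block is attached to the block's centre time, and a natural cubic spline
#' through these knots is evaluated at every frame and subtracted. The mean
#' of the spline is added back so the corrected trace keeps the original
#' baseline fluorescence level (F0) and overall mean.
#'
#' @param trace A [raw_trace()] (or [normalized_trace()]).
#' @param block_s Block width in seconds, default 25; the trace must span at
#'   least two blocks.
#' @return Trace of the same class, drift-corrected, same length.
#' @export
correct_drift <- function(trace, block_s = 25) {
  x <- trace$values; n <- length(x); fps <- trace$fps
  bf <- round(block_s * fps)
  n_blocks <- n %/% bf
  if (n_blocks < 2) stop_param("trace must span at least two ", block_s, "-s blocks")
  ## assign every frame to a block; trailing partial block joins the last one
  blk <- pmin((seq_len(n) - 1L) %/% bf + 1L, n_blocks)
  cnt <- as.numeric(rowsum(rep(1, n), blk))
  centers <- as.numeric(rowsum(as.numeric(seq_len(n)), blk)) / cnt  # block centre, frames
  means <- as.numeric(rowsum(x, blk)) / cnt
  sp <- spline(x = centers, y = means,
               xout = seq_len(n), method = "natural")$y
  trace$values <- x - sp + mean(sp)
  trace
}

#' Estimate the baseline fluorescence F0
#'
#' Robust baseline: by default the 10th percentile of the (drift-corrected)
#' trace, insensitive to sparse positive transients.
#'
#' @param trace A [raw_trace()].
#' @param probs Percentile in `[0, 1]`, default 0.10.
#' @return Baseline estimate, a.u. (strictly positive).
#' @export
estimate_f0 <- function(trace, probs = 0.10) {
  f0 <- as.numeric(quantile(trace$values, probs))
  if (!is.finite(f0) || f0 <= 0) {
    stop(errorCondition("degenerate baseline: F0 estimate is not positive",
                        class = c("caltrace_baseline_error", "error")))
  }
  f0
}

#' Normalize a trace to dF/F0 (%)
#'
#' `dF/F0 = 100 * (F* - F0) / F0`.
#'
#' @param trace A [raw_trace()].
#' @param f0 Baseline fluorescence, a.u.; must be > 0.
#' @return A [normalized_trace()].
#' @export
normalize_dff <- function(trace, f0) {
  assert_scalar_num(f0, "f0", 0, strict = TRUE)
  normalized_trace(100 * (trace$values - f0) / f0, f0, trace$fps)
}

#' Field-of-view extent
#'
#' @param n_pixels Number of pixels along one frame axis.
#' @param um_per_px Pixel pitch in micrometres.
#' @return Extent in millimetres (`n_pixels * um_per_px / 1000`).
#' @examples
#' fov_extent(960, 4.40)  # 4.224 mm
#' fov_extent(720, 4.40)  # 3.168 mm
#' @export
fov_extent <- function(n_pixels, um_per_px) {
  assert_scalar_num(n_pixels, "n_pixels", 0)
  assert_scalar_num(um_per_px, "um_per_px", 0)
  n_pixels * um_per_px / 1000
}

#' Process a raw trace to dF/F0
#'
#' Convenience chain: [smooth_trace()] -> [correct_drift()] ->
#' [estimate_f0()] -> [normalize_dff()].
#'
#' @param trace A [raw_trace()].
#' @param window_frames Moving-average width, frames.
#' @param block_s Drift-correction block width, s.
#' @param f0_probs Baseline percentile in `[0, 1]`.
#' @return A [normalized_trace()].
#' @export
process_trace <- function(trace, window_frames = 5, block_s = 25,
                          f0_probs = 0.10) {
  tr <- smooth_trace(trace, window_frames)
  tr <- correct_drift(tr, block_s)
  normalize_dff(tr, estimate_f0(tr, f0_probs))
}
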
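## Standard-format I/O: TIFF movies, CSV tables, JSON models.

#' Write a movie as a multi-frame 16-bit TIFF
#'
#' Intensities are stored as unsigned 16-bit samples; values are clipped to
#' `[0, 65535]`.
#'
#' @param movie A [movie_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  f <- movie$frames
  n <- dim(f)[1]
  frames <- lapply(seq_len(n), function(i) {
    m <- f[i, , ]
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-frame TIFF as a movie stack
#'
#' @param path TIFF file path.
#' @param geometry An [acquisition_geometry()] describing the recording;
#'   `duration` is recomputed from the frame count and `fps`.
#' @return A [movie_stack()] with intensities on the original 16-bit scale.
#' @export
read_movie_tiff <- function(path, geometry) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  arr <- array(0, dim = c(length(frames), h, w))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]] * 65535
  geometry$frame_shape <- c(h, w)
  geometry$duration <- length(frames) / geometry$fps
  movie_stack(arr, geometry)
}

#' Write traces to CSV
#'
#' Column 1 is `time_s`; the remaining columns hold one trace per ROI.
#'
#' @param traces List of [raw_trace()] or [normalized_trace()] objects with a
#'   common frame rate and length.
#' @param path Output CSV path.
#' @param ids Optional ROI ids (default `roi_1 ...`).
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, ids = NULL) {
  if (!length(traces)) stop_param("no traces to write")
  fps <- traces[[1]]$fps
  n <- length(traces[[1]]$values)
  ids <- ids %||% paste0("roi_", seq_along(traces))
  df <- data.frame(time_s = (seq_len(n) - 1L) / fps)
  for (i in seq_along(traces)) df[[ids[i]]] <- traces[[i]]$values
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from CSV
#'
#' @param path CSV with a `time_s` column followed by one column per ROI.
#' @param normalized If `TRUE`, return [normalized_trace()] objects
#'   (values already in % dF/F0; `f0` set to 100 as a placeholder scale),
#'   otherwise [raw_trace()].
#' @return Named list of traces.
#' @export
read_traces_csv <- function(path, normalized = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop_param("trace CSV must have a `time_s` column")
  t <- df$time_s
  if (length(t) < 2) stop_param("trace CSV needs at least two frames")
  fps <- 1 / median(diff(t))
  cols <- setdiff(names(df), "time_s")
  out <- lapply(cols, function(cn) {
    if (normalized) normalized_trace(df[[cn]], 100, fps) else raw_trace(df[[cn]], fps)
  })
  names(out) <- cols
  out
}

#' Write a spike table to CSV
#'
#' @param spikes List of [spike_train()] objects.
#' @param path Output CSV path (columns `neuron_id`, `time_s`).
#' @param ids Optional neuron ids.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spikes, path, ids = NULL) {
  ids <- ids %||% paste0("roi_", seq_along(spikes))
  rows <- do.call(rbind, lapply(seq_along(spikes), function(i) {
    tm <- spikes[[i]]$times
    if (!length(tm)) return(NULL)
    data.frame(neuron_id = ids[i], time_s = tm)
  }))
  if (is.null(rows)) rows <- data.frame(neuron_id = character(0), time_s = numeric(0))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a spike table from CSV
#'
#' @param path CSV with columns `neuron_id`, `time_s`.
#' @param duration Recording duration, s.
#' @param ids Optional vector of neuron ids to materialize (so silent neurons
#'   are kept as empty trains, in order).
#' @return Named list of [spike_train()].
#' @export
read_spikes_csv <- function(path, duration, ids = NULL) {
  df <- read.csv(path)
  ids <- ids %||% unique(df$neuron_id)
  out <- lapply(ids, function(id) {
    spike_train(df$time_s[df$neuron_id == id], duration)
  })
  names(out) <- ids
  out
}

#' Write an ROI table to CSV
#'
#' @param rois An [roi_set()].
#' @param path Output CSV (columns `roi_id`, `y_px`, `x_px`, `size_px`).
#' @return `path`, invisibly.
#' @export
write_rois_csv <- function(rois, path) {
  n <- nrow(rois$centers)
  df <- data.frame(roi_id = paste0("roi_", seq_len(n)),
                   y_px = rois$centers[, 1], x_px = rois$centers[, 2],
                   size_px = rois$size_px)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
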
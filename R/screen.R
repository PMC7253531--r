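## Active/inactive screening: trace-shape features plus a boosted-stump
## (discrete AdaBoost) classifier trained from a labelled subset.

#' Intervals of high activity in a normalized trace
#'
#' Maximal runs of frames whose dF/F0 value exceeds `threshold`, reported as
#' half-open intervals in seconds (`start = first frame / fps`,
#' `end = (last frame + 1) / fps`). Runs separated by any sub-threshold frame
#' are never merged.
#'
#' @param trace A [normalized_trace()].
#' @param threshold Threshold in % dF/F0.
#' @return Two-column matrix `(start_s, end_s)`, zero rows if none.
#' @export
high_activity_intervals <- function(trace, threshold) {
  assert_scalar_num(threshold, "threshold")
  above <- trace$values > threshold
  if (!any(above)) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start_s = (starts[keep] - 1L) / trace$fps,
        end_s = ends[keep] / trace$fps)
}

## Default screening threshold: 2x the robust noise SD (1.4826 * MAD).
default_screen_threshold <- function(trace) {
  2 * mad(trace$values)  # stats::mad already applies the 1.4826 constant
}

#' Trace-shape features for the activity screen
#'
#' Five features summarizing the supra-threshold structure of a trace:
#' fraction of time above threshold, number of high-activity intervals,
#' mean interval duration (s), maximum dF/F0 (%) and the signal SD (%).
#'
#' @param trace A [normalized_trace()].
#' @param threshold Threshold in % dF/F0; `NULL` (default) uses 2x the
#'   robust noise SD (1.4826 * MAD) of the trace.
#' @return Named numeric vector of length 5.
#' @export
screen_features <- function(trace, threshold = NULL) {
  threshold <- threshold %||% default_screen_threshold(trace)
  iv <- high_activity_intervals(trace, threshold)
  n <- length(trace$values)
  durs <- iv[, 2] - iv[, 1]
  c(frac_above = sum(trace$values > threshold) / n,
    n_intervals = nrow(iv),
    mean_interval_s = if (nrow(iv)) mean(durs) else 0,
    max_dff = max(trace$values),
    sd_dff = sd(trace$values))
}

#' Train the active/inactive boosting screen
#'
#' Discrete AdaBoost over depth-1 decision stumps. Each round fits the
#' best single-feature threshold split (either polarity) under the current
#' example weights and adds it with weight
#' `alpha = 0.5 * log((1 - err) / err)`.
#'
#' @param features Numeric matrix (rows = traces, columns = features) such
#'   as rows of [screen_features()].
#' @param labels Character/factor vector with levels `"active"`, `"inactive"`.
#' @param n_rounds Number of boosting rounds, default 50.
#' @param seed Integer seed (recorded; training itself is deterministic).
#' @return A `screen_model`: list of stumps with weights plus metadata.
#' @export
train_screen <- function(features, labels, n_rounds = 50, seed = 1) {
  x <- as.matrix(features)
  y <- ifelse(as.character(labels) == "active", 1, -1)
  if (length(unique(y)) < 2) {
    stop(errorCondition("training needs both active and inactive examples",
                        class = c("caltrace_training_error", "error")))
  }
  if (nrow(x) != length(y)) stop_param("features/labels length mismatch")
  n <- nrow(x); p <- ncol(x)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  train_err <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    best <- NULL; best_err <- Inf
    for (j in seq_len(p)) {
      v <- x[, j]
      cuts <- sort(unique(v))
      if (length(cuts) > 1) cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
      for (cut in cuts) {
        pred <- ifelse(v > cut, 1, -1)
        e_pos <- sum(w[pred != y])
        e_neg <- 1 - e_pos          # error of the flipped stump
        if (e_pos < best_err) {
          best_err <- e_pos
          best <- list(feature = j, cut = cut, polarity = 1)
        }
        if (e_neg < best_err) {
          best_err <- e_neg
          best <- list(feature = j, cut = cut, polarity = -1)
        }
      }
    }
    err <- max(best_err, 1e-12)
    alpha <- 0.5 * log((1 - err) / err)
    best$alpha <- alpha
    stumps[[r]] <- best
    pred <- best$polarity * ifelse(x[, best$feature] > best$cut, 1, -1)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    agg <- screen_margin(stumps[seq_len(r)], x)
    train_err[r] <- mean(sign(agg) * y < 0)
    if (best_err <= 1e-12) { stumps <- stumps[seq_len(r)]; train_err <- train_err[seq_len(r)]; break }
  }
  structure(
    list(stumps = stumps, feature_names = colnames(x), n_features = p,
         train_error = train_err,
         n_labeled = table(as.character(labels)), seed = seed),
    class = "screen_model"
  )
}

screen_margin <- function(stumps, x) {
  m <- numeric(nrow(x))
  for (s in stumps) {
    m <- m + s$alpha * s$polarity * ifelse(x[, s$feature] > s$cut, 1, -1)
  }
  m
}

#' Classify traces as active or inactive
#'
#' Sign of the weighted stump vote; a zero margin is classified `"active"`
#' (ties favour sensitivity).
#'
#' @param model A `screen_model` from [train_screen()].
#' @param features Numeric matrix of screen features (or a single vector).
#' @return `data.frame(label, margin)`, one row per trace.
#' @export
classify_screen <- function(model, features) {
  x <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  if (!is.null(model$n_features) && ncol(x) != model$n_features) {
    stop_param("feature dimension mismatch: model expects ",
               model$n_features, " features")
  }
  m <- screen_margin(model$stumps, x)
  data.frame(label = ifelse(m >= 0, "active", "inactive"), margin = m)
}

#' Save / load a screen model as JSON
#'
#' @param model A `screen_model`.
#' @param path JSON file path.
#' @return `path` invisibly (`write_screen_model`), or the model
#'   (`read_screen_model`).
#' @export
write_screen_model <- function(model, path) {
  obj <- list(
    stumps = lapply(model$stumps, function(s) s[c("feature", "cut", "polarity", "alpha")]),
    feature_names = model$feature_names,
    n_features = model$n_features,
    train_error = model$train_error,
    n_labeled = as.list(model$n_labeled),
    seed = model$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_screen_model
#' @export
read_screen_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  stumps <- lapply(obj$stumps, function(s) {
    list(feature = as.integer(s$feature), cut = s$cut,
         polarity = s$polarity, alpha = s$alpha)
  })
  structure(
    list(stumps = stumps, feature_names = obj$feature_names,
         n_features = obj$n_features,
         train_error = obj$train_error, n_labeled = obj$n_labeled,
         seed = obj$seed),
    class = "screen_model"
  )
}
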
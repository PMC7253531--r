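## Phenotype segregation: PCA of the nine-feature vectors, per-feature PC
## contributions, k-means grouping and mapping of groups to LF/IF/HF classes.

#' Fit a PCA model to a feature matrix
#'
#' Missing (undefined) feature values are imputed with the per-feature
#' median, features are centred and by default z-scored, and the data are
#' projected onto the eigenvectors of the covariance (via
#' [stats::prcomp()]), sorted by descending eigenvalue. The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' which makes contribution tables reproducible.
#'
#' @param features Numeric matrix or data.frame (rows = neurons); if a
#'   data.frame, only the nine standard feature columns are used.
#' @param standardize Z-score features first (default `TRUE`).
#' @return List with `model` (class `pca_model`: `center`, `scale`,
#'   `loadings`, `explained_variance`, `imputed_medians`, `feature_names`)
#'   and `scores` (matrix, neurons x components).
#' @export
fit_pca <- function(features, standardize = TRUE) {
  x <- as_feature_matrix(features)
  if (nrow(x) < 2 || ncol(x) < 2) stop_param("need >= 2 neurons and >= 2 features")
  med <- apply(x, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  keep_sd <- apply(x, 2, sd)
  if (all(keep_sd == 0)) {
    stop(errorCondition("degenerate data: no feature varies",
                        class = c("caltrace_degenerate_error", "error")))
  }
  ## constant features carry no variance; a zero scale would divide by zero
  scale_arg <- if (standardize) ifelse(keep_sd > 0, keep_sd, 1) else FALSE
  pc <- prcomp(x, center = TRUE, scale. = scale_arg)
  ## deterministic sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  model <- structure(
    list(center = pc$center,
         scale = if (standardize) scale_arg else rep(1, ncol(x)),
         loadings = pc$rotation,
         explained_variance = ev / sum(ev),
         imputed_medians = med,
         feature_names = colnames(x)),
    class = "pca_model"
  )
  list(model = model, scores = pc$x)
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- intersect(feature_names(), names(features))
    if (length(cols) >= 2) features <- features[, cols]
    x <- as.matrix(features)
  } else {
    x <- as.matrix(features)
  }
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Per-feature contribution to a principal component
#'
#' `100 * loading_i^2 / sum_j loading_j^2` for the chosen component; with
#' orthonormal loadings the contributions of one PC sum to exactly 100.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param pc_index Component index (1-based).
#' @return Named numeric vector of contributions in percent.
#' @export
pc_contributions <- function(model, pc_index) {
  if (pc_index < 1 || pc_index > ncol(model$loadings)) {
    stop(errorCondition("PC index out of range",
                        class = c("caltrace_index_error", "error")))
  }
  l <- model$loadings[, pc_index]
  100 * l^2 / sum(l^2)
}

#' K-means grouping of PC scores
#'
#' Lloyd's algorithm, best of `n_restarts` random starts (via
#' [stats::kmeans()]), deterministic for a fixed seed.
#'
#' @param scores Numeric matrix (neurons x components).
#' @param k Number of groups, default 8.
#' @param n_restarts Random restarts, default 50.
#' @param seed Integer seed.
#' @return List of class `cluster_assignment`: `labels` (1..k), `k`,
#'   `centroids`, `inertia` (total within-group sum of squares), `seed`.
#' @export
kmeans_cluster <- function(scores, k = 8, n_restarts = 50, seed = 1) {
  scores <- as.matrix(scores)
  if (nrow(scores) < k) stop_param("need at least k = ", k, " neurons, got ",
                                   nrow(scores))
  km <- with_seed(seed, suppressWarnings(
    kmeans(scores, centers = k, nstart = n_restarts, iter.max = 100,
           algorithm = "Lloyd")
  ))
  structure(
    list(labels = as.integer(km$cluster), k = as.integer(k),
         centroids = km$centers, inertia = km$tot.withinss, seed = seed),
    class = "cluster_assignment"
  )
}

#' Default group-to-class thresholds
#'
#' A k-means group is called high-firing (HF) when its median burst count is
#' at least `hf_b` or its median inter-burst interval is at most `hf_ibi_s`;
#' low-firing (LF) when its median burst count is at most `lf_b` or its
#' median IBI exceeds `lf_ibi_s`; intermediate (IF) otherwise. The defaults
#' follow the reported phenotype ranges: HF ~40-60 bursts with IBI 10-16 s,
#' LF 1-7 bursts, IF 7-17 bursts with IBI 27-60 s — hence the LF IBI bound
#' sits at 60 s, the upper edge of the IF range.
#'
#' The burst-count thresholds refer to a 10-min (600-s) recording window;
#' [classify_groups()] rescales observed burst counts to that window when
#' the feature table records a different duration.
#'
#' @return Named list `hf_b`, `hf_ibi_s`, `lf_b`, `lf_ibi_s`, `ref_window_s`.
#' @export
class_thresholds <- function() {
  list(hf_b = 40, hf_ibi_s = 16, lf_b = 7, lf_ibi_s = 60, ref_window_s = 600)
}

#' Map k-means groups to firing classes and build the phenotype report
#'
#' Each group is mapped to LF/IF/HF from its median burst count and median
#' inter-burst interval (see [class_thresholds()]). A group in which no
#' neuron bursts falls back to spike-count tertiles: its median `NS` is
#' placed against the population NS tertiles (lower third LF, upper third
#' HF). The report carries per-group feature summaries, the group-to-class
#' map and the class fractions of the population.
#'
#' @param assignment A `cluster_assignment` from [kmeans_cluster()].
#' @param features Feature `data.frame` (rows aligned with
#'   `assignment$labels`).
#' @param thresholds Threshold list, default [class_thresholds()].
#' @return List of class `phenotype_report`: `group_summaries`,
#'   `group_class`, `class_fractions`, `group_sizes`, `k`, `seed`.
#' @export
classify_groups <- function(assignment, features, thresholds = class_thresholds()) {
  labs <- assignment$labels
  if (length(labs) != NROW(features)) stop_param("assignment/features mismatch")
  groups <- sort(unique(labs))
  ns_terts <- quantile(features$NS, c(1 / 3, 2 / 3), na.rm = TRUE)
  g_class <- character(length(groups))
  g_summ <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    fv <- features[labs == g, , drop = FALSE]
    g_summ[[as.character(g)]] <- summarize_group(fv)
    med_b <- median(fv$B, na.rm = TRUE)
    if (!is.null(fv$duration_s)) {
      ## burst-count thresholds are stated per reference (10-min) window
      med_b <- med_b * thresholds$ref_window_s / median(fv$duration_s)
    }
    med_ibi <- suppressWarnings(median(fv$IBI, na.rm = TRUE))
    if (!any(fv$B > 0, na.rm = TRUE)) {
      ## no bursting member: fall back to population NS tertiles
      med_ns <- median(fv$NS, na.rm = TRUE)
      g_class[gi] <- if (med_ns <= ns_terts[1]) "LF"
                     else if (med_ns > ns_terts[2]) "HF" else "IF"
    } else if (med_b >= thresholds$hf_b ||
               (is.finite(med_ibi) && med_ibi <= thresholds$hf_ibi_s)) {
      g_class[gi] <- "HF"
    } else if (med_b <= thresholds$lf_b ||
               (is.finite(med_ibi) && med_ibi > thresholds$lf_ibi_s)) {
      g_class[gi] <- "LF"
    } else {
      g_class[gi] <- "IF"
    }
  }
  names(g_class) <- groups
  cls <- g_class[as.character(labs)]
  frac <- table(factor(cls, levels = c("LF", "IF", "HF"))) / length(cls)
  structure(
    list(group_summaries = g_summ, group_class = g_class,
         class_fractions = as.numeric(frac) |> stats::setNames(c("LF", "IF", "HF")),
         group_sizes = as.integer(table(factor(labs, levels = groups))),
         k = assignment$k, seed = assignment$seed),
    class = "phenotype_report"
  )
}

#' Write a phenotype report to JSON
#'
#' @param report A `phenotype_report`.
#' @param pca A `pca_model` (optional), stored with loadings and
#'   per-PC contributions.
#' @param path Output JSON path.
#' @param config Optional config echo.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, pca = NULL, path, config = NULL) {
  obj <- list(
    k = report$k, seed = report$seed,
    group_class = as.list(report$group_class),
    class_fractions = as.list(report$class_fractions),
    group_sizes = report$group_sizes,
    group_summaries = lapply(report$group_summaries, function(s) {
      lapply(split(s, s$feature), function(r) {
        list(mean = r$mean, sd = r$sd, sem = r$sem, n = r$n)
      })
    })
  )
  if (!is.null(pca)) {
    obj$pca <- list(
      feature_names = pca$feature_names,
      loadings = unname(apply(pca$loadings, 2, as.numeric, simplify = FALSE)),
      explained_variance = pca$explained_variance,
      contributions = lapply(seq_len(ncol(pca$loadings)),
                             function(j) as.list(pc_contributions(pca, j)))
    )
  }
  if (!is.null(config)) obj$config <- config
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
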
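#' Labeled fingerprint sets
#'
#' Pairs a ternary fingerprint matrix with one class label per sample
#' (tissue, species, platform...). Input to the benchmark suite.
#'
#' @param prints A `fingerprint_matrix` or ternary matrix (pathways x samples).
#' @param labels Character/factor vector, one label per sample column.
#' @return An object of class `labeled_prints`.
#' @export
labeled_prints <- function(prints, labels) {
  m <- as_score_matrix(prints)
  if (length(labels) != ncol(m)) abort("one label per sample required")
  structure(list(scores = m, labels = as.character(labels)),
            class = "labeled_prints")
}

dist_to_centroid <- function(m, centroid, metric) {
  # m: pathways x samples; centroid: pathways vector
  if (metric == "euclidean") sqrt(colSums((m - centroid)^2))
  else colSums(abs(m - centroid))
}

class_centroids <- function(m, labels) {
  classes <- sort(unique(labels))
  cent <- vapply(classes, function(cl) rowMeans(m[, labels == cl, drop = FALSE]),
                 numeric(nrow(m)))
  colnames(cent) <- classes
  cent
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Nearest-mean-fingerprint cross-validation
#'
#' Samples are split into `k` stratified folds; each held-out sample is
#' assigned to the class whose mean training fingerprint is closest
#' (Euclidean or Manhattan), and the error rate is the misassignment
#' fraction. The procedure is repeated `repeats` times with fresh folds to
#' estimate a mean and SD. If any class has fewer than `k` members the
#' procedure falls back to leave-one-out cross-validation.
#'
#' @param data A `labeled_prints` with >= 2 classes.
#' @param k Number of folds (default 5).
#' @param repeats Number of repetitions (default 10; forced to 1 for LOO).
#' @param metric "euclidean" (default) or "manhattan".
#' @param seed Integer seed.
#' @return A one-row tibble `(error_rate, sd, k, repeats, n_samples, method)`.
#' @export
nearest_centroid_cv <- function(data, k = 5, repeats = 10,
                                metric = c("euclidean", "manhattan"), seed = 1) {
  stopifnot(inherits(data, "labeled_prints"))
  metric <- match.arg(metric)
  labels <- data$labels
  if (length(unique(labels)) < 2L) abort("cross-validation needs >= 2 classes")
  m <- data$scores
  loo <- min(table(labels)) < k
  if (loo) {
    k <- ncol(m)
    repeats <- 1L
  }
  errs <- withr::with_seed(seed, vapply(seq_len(repeats), function(r) {
    fold <- if (loo) seq_len(ncol(m)) else stratified_folds(labels, k)
    wrong <- 0L
    for (f in sort(unique(fold))) {
      test <- which(fold == f)
      train <- which(fold != f)
      cent <- class_centroids(m[, train, drop = FALSE], labels[train])
      d <- vapply(seq_len(ncol(cent)), function(j) {
        dist_to_centroid(m[, test, drop = FALSE], cent[, j], metric)
      }, numeric(length(test)))
      if (length(test) == 1L) d <- matrix(d, nrow = 1L)
      pred <- colnames(cent)[apply(d, 1L, which.min)]
      wrong <- wrong + sum(pred != labels[test])
    }
    wrong / ncol(m)
  }, 0))
  tibble(error_rate = mean(errs), sd = sd(errs), k = k,
         repeats = repeats, n_samples = ncol(m),
         method = if (loo) "leave-one-out" else "k-fold")
}

#' Cluster validity: intra- over inter-class variance
#'
#' Intra-class variance is the sum over samples of the squared Euclidean
#' distance to the sample's own class mean fingerprint; inter-class variance
#' is the sum over samples of the mean squared Euclidean distance to the
#' other classes' means. A lower ratio indicates tighter clustering within
#' classes and/or better separation between them. Classes with a single
#' member are excluded from the intra term with a warning. When the class
#' means coincide (inter = 0) the ratio is reported as `Inf`.
#'
#' @param data A `labeled_prints` with >= 2 classes.
#' @return A one-row tibble `(ratio, intra, inter)`.
#' @export
cluster_validity <- function(data) {
  stopifnot(inherits(data, "labeled_prints"))
  m <- data$scores
  labels <- data$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L) abort("cluster validity needs >= 2 classes")
  cent <- class_centroids(m, labels)
  singletons <- names(which(table(labels) == 1L))
  if (length(singletons) > 0L) {
    warn(paste0("classes with one member excluded from intra-class variance: ",
                paste(singletons, collapse = ", ")))
  }
  intra <- 0
  inter <- 0
  for (i in seq_len(ncol(m))) {
    own <- labels[i]
    if (!(own %in% singletons)) {
      intra <- intra + sum((m[, i] - cent[, own])^2)
    }
    others <- setdiff(classes, own)
    inter <- inter + mean(vapply(others, function(cl) sum((m[, i] - cent[, cl])^2), 0))
  }
  tibble(ratio = if (inter == 0) Inf else intra / inter,
         intra = intra, inter = inter)
}

interpolated_ap <- function(rel) {
  # rel: logical relevance down the ranked list; AP = mean over the true
  # matches of the interpolated precision at their recall points, with
  # p(r) = max precision at recall >= r.
  if (!any(rel)) return(NA_real_)
  prec <- cumsum(rel) / seq_along(rel)
  prec_at_hits <- prec[rel]
  interp <- rev(cummax(rev(prec_at_hits)))
  mean(interp)
}

#' Retrieval benchmark: interpolated precision-recall and MAP
#'
#' Every sample queries the rest of the corpus; the corpus is ranked by
#' distance from the query (self excluded, ties broken by sample id), and
#' same-class samples are the relevant items. Average precision per query
#' uses the standard interpolation `p(r) = max precision at recall >= r`;
#' MAP is the mean over all queries. Queries whose class has no other
#' member are skipped with a warning.
#'
#' @param data A `labeled_prints` with >= 2 classes.
#' @param metric "manhattan" (default) or "euclidean".
#' @param recall_grid Recall points for the averaged per-class curves.
#' @return A list: `map` (numeric), `per_query` tibble
#'   `(sample, label, average_precision)`, and `curves` tibble
#'   `(label, recall, precision)` of per-class mean interpolated curves.
#' @export
retrieval_pr <- function(data, metric = c("manhattan", "euclidean"),
                         recall_grid = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(data, "labeled_prints"))
  metric <- match.arg(metric)
  m <- data$scores
  labels <- data$labels
  if (length(unique(labels)) < 2L) abort("retrieval needs >= 2 classes")
  ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
  n <- ncol(m)
  ap <- rep(NA_real_, n)
  curve_rows <- vector("list", n)
  skipped <- character()
  for (i in seq_len(n)) {
    rel_pool <- labels == labels[i]
    rel_pool[i] <- FALSE
    if (!any(rel_pool)) {
      skipped <- c(skipped, ids[i])
      next
    }
    d <- dist_to_centroid(m[, -i, drop = FALSE], m[, i], metric)
    ord <- order(d, ids[-i])
    rel <- rel_pool[-i][ord]
    ap[i] <- interpolated_ap(rel)
    prec <- cumsum(rel) / seq_along(rel)
    recall <- cumsum(rel) / sum(rel)
    p_at <- vapply(recall_grid, function(r) {
      ok <- recall >= r
      if (any(ok)) max(prec[ok]) else 0
    }, 0)
    curve_rows[[i]] <- tibble(label = labels[i], recall = recall_grid,
                              precision = p_at)
  }
  if (length(skipped) > 0L) {
    warn(paste0("queries skipped (singleton class): ", paste(skipped, collapse = ", ")))
  }
  per_query <- tibble(sample = ids, label = labels, average_precision = ap)
  curves <- bind_rows(curve_rows)
  curves <- summarise(group_by(curves, .data$label, .data$recall),
                      precision = mean(.data$precision), .groups = "drop")
  list(map = mean(ap, na.rm = TRUE), per_query = per_query, curves = curves)
}

#' Plot averaged precision-recall curves
#' @param curves The `curves` tibble from [retrieval_pr()].
#' @return A ggplot.
#' @export
plot_pr_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$recall, .data$precision,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "interpolated precision")
}

#' Sweep the ternary threshold over the benchmark metrics
#'
#' Re-ternarizes the same POE matrix at each threshold and computes the
#' cross-validation error, cluster validity ratio and MAP, optionally also
#' for a size-matched random-gene-set comparator POE matrix. Used to choose
#' the ternary threshold: performance typically improves as the threshold is
#' relaxed, flattening out at small values.
#'
#' @param poe A `poe_matrix` (or plain POE matrix) for the real collection.
#' @param labels One class label per sample.
#' @param thresholds Numeric vector of thresholds in (0, 1).
#' @param poe_random Optional comparator POE matrix computed from
#'   size-matched random gene sets (see [random_genesets()]).
#' @param metric Distance metric for CV and retrieval.
#' @param cv_folds,cv_repeats Passed to [nearest_centroid_cv()].
#' @param seed Integer seed for fold assignment.
#' @return A tibble with one row per (threshold, collection) combination and
#'   columns `threshold, collection, cv_error, cv_sd, validity_ratio, map`.
#' @export
threshold_sweep <- function(poe, labels, thresholds, poe_random = NULL,
                            metric = c("manhattan", "euclidean"),
                            cv_folds = 5, cv_repeats = 3, seed = 1) {
  metric <- match.arg(metric)
  if (any(thresholds <= 0 | thresholds >= 1)) abort("thresholds must be in (0, 1)")
  sources <- list(real = poe)
  if (!is.null(poe_random)) sources$random <- poe_random
  rows <- list()
  for (src in names(sources)) {
    for (th in thresholds) {
      lp <- labeled_prints(ternarize(sources[[src]], threshold = th), labels)
      cv <- nearest_centroid_cv(lp, k = cv_folds, repeats = cv_repeats,
                                metric = if (metric == "manhattan") "manhattan" else "euclidean",
                                seed = seed)
      cvr <- cluster_validity(lp)
      pr <- retrieval_pr(lp, metric = metric)
      rows[[length(rows) + 1L]] <- tibble(
        threshold = th, collection = src,
        cv_error = cv$error_rate, cv_sd = cv$sd,
        validity_ratio = cvr$ratio, map = pr$map
      )
    }
  }
  bind_rows(rows)
}
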
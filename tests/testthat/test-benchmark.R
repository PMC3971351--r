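# Two-class ternary fixture with tunable overlap between class blocks.
two_class_prints <- function(n_per = 10, n_path = 30, flip = 0, seed = 1) {
  withr::with_seed(seed, {
    a <- c(rep(1L, n_path / 2), rep(-1L, n_path / 2))
    b <- -a
    jitter <- function(v) {
      if (flip > 0) {
        idx <- sample(n_path, flip)
        v[idx] <- sample(c(-1L, 0L, 1L), flip, replace = TRUE)
      }
      v
    }
    m <- cbind(vapply(1:n_per, function(i) jitter(a), a),
               vapply(1:n_per, function(i) jitter(b), b))
    dimnames(m) <- list(paste0("p", 1:n_path), sprintf("s%02d", 1:(2 * n_per)))
    labeled_prints(m, rep(c("A", "B"), each = n_per))
  })
}

test_that("cross-validation separates disjoint classes and reports spread", {
  lp <- two_class_prints(flip = 2)
  cv <- nearest_centroid_cv(lp, seed = 5)
  expect_equal(cv$error_rate, 0)
  expect_equal(cv$repeats, 10)
  expect_false(is.na(cv$sd))
  expect_error(nearest_centroid_cv(labeled_prints(lp$scores, rep("A", 20))),
               "2 classes")
})

test_that("cross-validation error is near chance when prints carry no signal", {
  # iid ternary prints with balanced random labels: expected error 0.5
  m <- withr::with_seed(99, matrix(sample(c(-1L, 0L, 1L), 30 * 60, replace = TRUE),
                                   30, 60,
                                   dimnames = list(paste0("p", 1:30),
                                                   sprintf("s%02d", 1:60))))
  lp <- labeled_prints(m, rep(c("A", "B"), each = 30))
  cv <- nearest_centroid_cv(lp, repeats = 10, seed = 17)
  expect_lt(abs(cv$error_rate - 0.5), 0.15)
})

test_that("small classes trigger the leave-one-out fallback", {
  lp <- two_class_prints(n_per = 3, flip = 1)
  cv <- nearest_centroid_cv(lp, k = 5, seed = 2)
  expect_equal(cv$method, "leave-one-out")
  expect_equal(cv$k, 6)
})

test_that("cluster validity ratio behaves at the degenerate extremes", {
  # every sample at its class centroid: zero intra-class variance
  a <- rep(1L, 10)
  b <- rep(-1L, 10)
  m <- cbind(a, a, a, b, b, b)
  rownames(m) <- paste0("p", 1:10)
  lp <- labeled_prints(m, rep(c("A", "B"), each = 3))
  expect_equal(cluster_validity(lp)$ratio, 0)
  # identical samples in all classes: inter -> 0, ratio reported as Inf
  same <- labeled_prints(cbind(a, a, a, a), rep(c("A", "B"), each = 2))
  expect_equal(cluster_validity(same)$ratio, Inf)
})

test_that("cluster validity decreases monotonically with class separation", {
  ratios <- vapply(c(15, 8, 3, 0), function(fl) {
    cluster_validity(two_class_prints(n_per = 15, flip = fl, seed = 42))$ratio
  }, 0)
  expect_true(all(diff(ratios) < 0))
})

test_that("average precision matches the hand-enumerated oracle", {
  # ranked relevance (+,-,+,-) with 2 relevant: AP = (1 + 2/3)/2
  expect_equal(brute_ap(c(TRUE, FALSE, TRUE, FALSE)), (1 + 2 / 3) / 2)
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    m <- matrix(sample(c(-1L, 0L, 1L), 8 * n, replace = TRUE), 8, n,
                dimnames = list(paste0("p", 1:8), sprintf("s%02d", 1:n)))
    labels <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    data <- labeled_prints(m, labels)
    res <- suppressWarnings(retrieval_pr(data))
    for (i in seq_len(n)) {
      rel_pool <- labels == labels[i]
      rel_pool[i] <- FALSE
      if (!any(rel_pool)) next
      d <- colSums(abs(m[, -i, drop = FALSE] - m[, i]))
      ids <- colnames(m)[-i]
      rel <- rel_pool[-i][order(d, ids)]
      expect_equal(res$per_query$average_precision[i], brute_ap(rel))
    }
  }
})

test_that("retrieval MAP is 1 for separated classes and prevalence under permutation", {
  lp <- two_class_prints(n_per = 12, flip = 2)
  expect_equal(retrieval_pr(lp)$map, 1)
  # signal-free prints: MAP falls toward the class prevalence (the
  # interpolation convention biases it upward by a small finite-list term)
  m <- withr::with_seed(5, matrix(sample(c(-1L, 0L, 1L), 30 * 60, replace = TRUE),
                                  30, 60,
                                  dimnames = list(paste0("p", 1:30),
                                                  sprintf("s%02d", 1:60))))
  rnd <- labeled_prints(m, rep(c("A", "B"), each = 30))
  expect_lt(abs(retrieval_pr(rnd)$map - 0.5), 0.12)
})

test_that("threshold sweep returns complete rows and the published ordering", {
  fx <- test_corpus_fingerprints()
  fc <- fx$fc
  sweep <- threshold_sweep(fc$poe, fc$labels, thresholds = c(0.001, 0.5, 0.9),
                           cv_repeats = 2, seed = 3)
  expect_equal(nrow(sweep), 3)
  expect_true(all(c("cv_error", "validity_ratio", "map") %in% names(sweep)))
  map_low <- sweep$map[sweep$threshold == 0.001]
  map_high <- sweep$map[sweep$threshold == 0.9]
  expect_gte(map_low, map_high)   # relaxing the threshold helps
  expect_error(threshold_sweep(fc$poe, fc$labels, thresholds = 1.5), "thresholds")
})
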
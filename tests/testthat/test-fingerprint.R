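test_that("ternarization is boundary-inclusive with the published threshold", {
  poe <- c(a = 0.001, b = 0, c = -0.5, d = 0.0009, e = -0.001)
  f <- ternarize(poe, threshold = 0.001)
  expect_equal(unname(f$scores[, 1]), c(1L, 0L, -1L, 0L, -1L))
  strict <- ternarize(c(a = 0.5), threshold = 0.9)
  expect_equal(unname(strict$scores[, 1]), 0L)
  expect_error(ternarize(poe, threshold = 0), "threshold")
})

test_that("ternarization is odd and tracks unmeasured pathways as zero", {
  set.seed(3)
  poe <- matrix(runif(30, -1, 1), 10, 3,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:3)))
  poe[2, 1] <- NA
  f_pos <- ternarize(poe, 0.2)
  f_neg <- ternarize(-poe, 0.2)
  expect_equal(f_neg$scores[-2, ], -f_pos$scores[-2, ])
  expect_equal(f_pos$scores[2, 1], 0L)
  expect_true(f_pos$unmeasured[2, 1])
})

test_that("consensus applies strict-inequality rules on the group mean", {
  m <- function(x) matrix(x, nrow = 1, dimnames = list("p", NULL))
  expect_equal(unname(consensus_fingerprint(m(c(1, 1, 1, 1)), 0.75)$scores), 1L)
  expect_equal(unname(consensus_fingerprint(m(c(1, 1, 1, 0)), 0.75)$scores), 0L)  # mu = t
  expect_equal(unname(consensus_fingerprint(m(c(-1, -1, -1, 0)), 0.5)$scores), -1L)
  # consensus of identical fingerprints is that fingerprint for any t < 1
  v <- c(a = 1L, b = -1L, c = 0L)
  mm <- matrix(rep(v, 5), ncol = 5, dimnames = list(names(v), NULL))
  for (t in c(0.1, 0.5, 0.99)) {
    expect_equal(consensus_fingerprint(mm, t)$scores, v)
  }
})

test_that("normalized Manhattan distance matches the stated formula", {
  expect_equal(fingerprint_distance(c(1, 0, -1), c(1, 0, -1))$distance, 0)
  expect_equal(fingerprint_distance(rep(1, 4), rep(-1, 4))$distance, 1)
  expect_equal(fingerprint_distance(c(1, 0), c(0, 1))$distance, 0.5)
  expect_error(fingerprint_distance(c(1, 0), c(1, 0, 0)), "length")
})

test_that("distance satisfies the metric axioms exhaustively at short lengths", {
  for (len in 1:4) {
    vecs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), len)))
    n <- nrow(vecs)
    d <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      d[i, j] <- fingerprint_distance(vecs[i, ], vecs[j, ])$distance
    }
    expect_true(all(d >= 0 & d <= 1))
    expect_identical(d, t(d))                         # symmetry
    expect_true(all((d == 0) == (outer(1:n, 1:n, function(i, j) {
      rowSums(abs(vecs[i, , drop = FALSE] - vecs[j, , drop = FALSE])) == 0
    }))))                                             # identity of indiscernibles
  }
  # triangle inequality: exhaustive at length 2, sampled at length 4
  vecs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 2)))
  for (i in seq_len(nrow(vecs))) for (j in seq_len(nrow(vecs))) for (k in seq_len(nrow(vecs))) {
    expect_lte(fingerprint_distance(vecs[i, ], vecs[j, ])$distance,
               fingerprint_distance(vecs[i, ], vecs[k, ])$distance +
                 fingerprint_distance(vecs[k, ], vecs[j, ])$distance + 1e-12)
  }
  set.seed(8)
  for (rep in 1:200) {
    a <- sample(c(-1, 0, 1), 4, replace = TRUE)
    b <- sample(c(-1, 0, 1), 4, replace = TRUE)
    cc <- sample(c(-1, 0, 1), 4, replace = TRUE)
    expect_lte(fingerprint_distance(a, b)$distance,
               fingerprint_distance(a, cc)$distance +
                 fingerprint_distance(cc, b)$distance + 1e-12)
  }
})

test_that("consensus-restricted distance ignores zero consensus coordinates", {
  cons <- structure(list(scores = c(p1 = 1L, p2 = 0L, p3 = -1L),
                         t = 0.5, n_samples = 4L),
                    class = "consensus_fingerprint")
  expect_equal(consensus_distance(cons, c(1, 1, -1))$distance, 0)
  expect_equal(consensus_distance(cons, c(-1, 0, 1))$distance, 1)
  expect_equal(consensus_distance(cons, c(1, 1, -1))$n_compared, 2)
  cons4 <- structure(list(scores = c(1L, 1L, 0L, 0L), t = 0.5, n_samples = 2L),
                     class = "consensus_fingerprint")
  expect_equal(consensus_distance(cons4, c(1, 0, 1, 1))$distance, 0.25)
  zero <- structure(list(scores = c(0L, 0L), t = 0.5, n_samples = 1L),
                    class = "consensus_fingerprint")
  expect_error(consensus_distance(zero, c(1, 0)), "informative")
})

test_that("retrieval p-values follow the IQR-normal null", {
  # quartile-symmetric vector: median - Q1 = IQR/2 exactly
  d <- c(seq(0.1, 0.5, length.out = 41))
  expect_equal(distance_pvalue(d, median(d)), 0.5)
  q1 <- unname(quantile(d, 0.25))
  expect_equal(distance_pvalue(d, q1), pnorm(-0.6745), tolerance = 1e-4)
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(distance_pvalue(d, grid)) >= 0))
  expect_error(distance_pvalue(rep(c(0.2, 0.2), 20)), "IQR")
  expect_error(distance_pvalue(c(0.1, 0.2)), ">= 20")
})

test_that("corpus ranking is deterministic, order-invariant and finds itself", {
  set.seed(12)
  n_path <- 30
  cons_v <- sample(c(-1L, 0L, 1L), n_path, replace = TRUE)
  cons_v[1:5] <- 1L
  corpus <- matrix(sample(c(-1L, 0L, 1L), n_path * 40, replace = TRUE),
                   n_path, 40,
                   dimnames = list(paste0("p", 1:n_path), sprintf("s%02d", 1:40)))
  corpus[, "s01"] <- cons_v
  cons <- consensus_fingerprint(matrix(rep(cons_v, 3), ncol = 3,
                                       dimnames = list(paste0("p", 1:n_path), NULL)),
                                t = 0.5)
  ranked <- rank_corpus(cons, corpus)
  expect_equal(ranked$sample[1], "s01")
  expect_equal(ranked$distance[1], 0)
  shuffled <- corpus[, sample(ncol(corpus))]
  expect_equal(rank_corpus(cons, shuffled), ranked)
})

test_that("fingerprint matrices round-trip through TSV", {
  set.seed(4)
  m <- matrix(sample(c(-1L, 0L, 1L), 50, replace = TRUE), 10, 5,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(m, path)
  expect_identical(read_fingerprints(path)$scores, m)
})
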
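# Fingerprint matrix realizing chosen consensus patterns per group.
grouped_fixture <- function(patterns, n_per = 4) {
  # patterns: list(leukemic_stem=, normal_stem=, progenitor=) ternary vectors
  groups <- rep(names(patterns), each = n_per)
  m <- do.call(cbind, lapply(names(patterns), function(g) {
    matrix(rep(patterns[[g]], n_per), ncol = n_per)
  }))
  rownames(m) <- names(patterns[[1]])
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  list(m = m, groups = groups)
}

test_that("the stem-versus-progenitor rule selects and signs pathways", {
  pw <- c(p_in = 1L, p_disagree = 1L, p_flat = 1L, p_down = -1L, p_zero = 0L)
  fx <- grouped_fixture(list(
    leukemic_stem = c(p_in = 1L, p_disagree = 1L, p_flat = 1L, p_down = -1L, p_zero = 0L),
    normal_stem   = c(p_in = 1L, p_disagree = -1L, p_flat = 1L, p_down = -1L, p_zero = 0L),
    progenitor    = c(p_in = 0L, p_disagree = 0L, p_flat = 1L, p_down = 1L, p_zero = 0L)))
  sig <- differential_signature(fx$m, fx$groups)
  expect_setequal(sig$pathway, c("p_in", "p_down"))
  expect_equal(sig$sign[sig$pathway == "p_in"], 1L)
  expect_equal(sig$sign[sig$pathway == "p_down"], -1L)
  # symmetric in the two stem groups
  swapped <- fx$groups
  swapped[fx$groups == "leukemic_stem"] <- "normal_stem"
  swapped[fx$groups == "normal_stem"] <- "leukemic_stem"
  expect_equal(differential_signature(fx$m, swapped), sig)
  # empty result warns rather than errors
  flat <- grouped_fixture(list(leukemic_stem = c(p = 1L), normal_stem = c(p = 1L),
                               progenitor = c(p = 1L)))
  expect_warning(empty <- differential_signature(flat$m, flat$groups), "empty")
  expect_equal(nrow(empty), 0)
  expect_error(differential_signature(fx$m, rep("progenitor", ncol(fx$m))),
               "empty group")
})

test_that("signature intersection keeps shared pathways with matching signs", {
  a <- pathway_signature(c("P1", "P2"), c(1L, -1L))
  b <- pathway_signature(c("P2", "P3"), c(-1L, 1L))
  expect_equal(intersect_signatures(a, b),
               pathway_signature("P2", -1L))
  conflict <- pathway_signature("P1", -1L)
  expect_equal(nrow(intersect_signatures(a, conflict)), 0)
  expect_equal(intersect_signatures(a, a), a)
})

test_that("signature scores are plain ternary sums with attainable bounds", {
  v <- c(p1 = 1L, p2 = 1L, p3 = 0L, p4 = -1L)
  sig <- pathway_signature(names(v), c(1L, 1L, 1L, 1L))
  expect_equal(unname(sras_score(v, sig)), 1L)
  expect_equal(unname(sras_score(setNames(rep(0L, 4), names(v)), sig)), 0L)
  expect_equal(unname(sras_score(setNames(rep(1L, 4), names(v)), sig)), 4L)
  expect_equal(unname(sras_score(setNames(rep(-1L, 4), names(v)), sig)), -4L)
  # additive over disjoint signatures
  s1 <- pathway_signature(c("p1", "p2"), c(1L, 1L))
  s2 <- pathway_signature(c("p3", "p4"), c(1L, 1L))
  expect_equal(sras_score(v, s1) + sras_score(v, s2), sras_score(v, sig))
  # sign-weighted variant
  wsig <- pathway_signature(names(v), c(1L, -1L, 1L, -1L))
  expect_equal(unname(sras_score(v, wsig, weighted = TRUE)), 1L - 1L + 0L + 1L)
  expect_error(sras_score(v, pathway_signature("nope", 1L)), "absent")
})

test_that("exact 1-D 2-means matches exhaustive split search", {
  grp <- stratify_two_groups(c(0, 0, 0, 4, 4, 4))
  expect_equal(as.character(grp), rep(c("low", "high"), each = 3))
  set.seed(55)
  for (rep in 1:100) {
    x <- round(rnorm(sample(5:40, 1), sd = 3))
    if (length(unique(x)) < 2) next
    expect_equal(attr(stratify_two_groups(x), "cut"), brute_two_means(x))
  }
  x <- rnorm(30)
  grp <- stratify_two_groups(x)
  expect_gt(mean(x[grp == "high"]), mean(x[grp == "low"]))
  expect_error(stratify_two_groups(rep(2, 10)), "identical")
})

test_that("log-rank matches the hand hypergeometric tally on the toy fixture", {
  surv <- survival_table(paste0("s", 1:6), c(1, 2, 3, 4, 5, 6), rep(1L, 6))
  groups <- rep(c("A", "B"), each = 3)
  res <- logrank_test(groups, surv)
  # hand tally: O_A = 3, E_A = 0.5 + 0.4 + 0.25, V = 0.25 + 0.24 + 0.1875
  expect_equal(res$statistic, (3 - 1.15)^2 / 0.6775, tolerance = 1e-10)
  expect_equal(res$statistic, brute_logrank(surv$time, surv$event, groups))
  # label swap leaves the statistic unchanged
  expect_equal(logrank_test(rev(groups), surv)$statistic, res$statistic)
})

test_that("log-rank handles identical groups and refuses degenerate input", {
  surv <- survival_table(paste0("s", 1:8), rep(c(1, 3, 5, 7), 2),
                         rep(c(1L, 1L, 0L, 1L), 2))
  groups <- rep(c("A", "B"), each = 4)  # same survival experience duplicated
  res <- logrank_test(groups, surv)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(rep("A", 8), surv), "two non-empty groups")
  nosurv <- survival_table(paste0("s", 1:8), rep(1, 8), rep(0L, 8))
  expect_error(logrank_test(groups, nosurv), "events")
})

test_that("permutation background is reproducible and detects a planted link", {
  set.seed(66)
  n_path <- 40
  n_samp <- 80
  m <- matrix(sample(c(-1L, 0L, 1L), n_path * n_samp, replace = TRUE),
              n_path, n_samp,
              dimnames = list(sprintf("pw%02d", 1:n_path), paste0("s", 1:n_samp)))
  sig <- pathway_signature(rownames(m)[1:5], rep(1L, 5))
  scores <- sras_score(m, sig)
  surv <- make_survival(scores, beta = 1, censor_rate = 0.2, seed = 3)
  bgd <- permutation_background(m, surv, sig, n_perm = 10, seed = 9)
  bgd2 <- permutation_background(m, surv, sig, n_perm = 10, seed = 9)
  expect_identical(bgd$p_values, bgd2$p_values)
  expect_identical(bgd$observed_p, bgd2$observed_p)
  full <- permutation_background(m, surv, sig, n_perm = 100, seed = 10)
  expect_lt(full$percentile, 0.05)   # planted signature beats the background
  expect_error(permutation_background(m, surv, n_path + 1, n_perm = 2, seed = 1),
               "exceeds")
})
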
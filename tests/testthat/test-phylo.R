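test_that("state cost matrices are validated", {
  costs <- state_cost_matrix()
  expect_equal(unname(costs["-1", "1"]), 2)
  expect_equal(unname(diag(costs)), c(0, 0, 0))
  bad <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3)
  expect_error(state_cost_matrix(bad), "diagonal")
  asym <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3)
  expect_error(state_cost_matrix(asym), "symmetric")
  spiky <- matrix(c(0, 1, 9, 1, 0, 1, 9, 1, 0), 3, 3)
  expect_error(state_cost_matrix(spiky), "triangle")
})

test_that("Sankoff score is exact on hand-checkable trees", {
  tree3 <- ape::read.tree(text = "(A,B,C);")
  uniform <- character_matrix(matrix(1L, 3, 1, dimnames = list(c("A", "B", "C"), "c1")))
  expect_equal(sankoff_score(tree3, uniform), 0)
  split <- character_matrix(matrix(c(-1L, 1L, 1L), 3, 1,
                                   dimnames = list(c("A", "B", "C"), "c1")))
  expect_equal(sankoff_score(tree3, split), 2)  # one -1 -> +1 transition
  expect_error(sankoff_score(tree3, character_matrix(
    matrix(1L, 3, 1, dimnames = list(c("A", "B", "X"), "c1")))), "tip labels")
})

test_that("Sankoff DP equals exhaustive internal-state enumeration", {
  costs <- state_cost_matrix()
  set.seed(15)
  for (rep in 1:20) {
    ntaxa <- sample(4:5, 1)
    tree <- ape::rtree(ntaxa, tip.label = LETTERS[1:ntaxa])
    m <- matrix(sample(c(-1L, 0L, 1L), ntaxa * 8, replace = TRUE), ntaxa, 8,
                dimnames = list(LETTERS[1:ntaxa], paste0("c", 1:8)))
    data <- character_matrix(m)
    expect_equal(sankoff_score(tree, data, costs), brute_sankoff(tree, data, costs))
  }
})

test_that("Sankoff score agrees with an independent parsimony engine", {
  set.seed(23)
  tree <- ape::rtree(7, tip.label = LETTERS[1:7])
  m <- matrix(sample(c(-1L, 0L, 1L), 7 * 20, replace = TRUE), 7, 20,
              dimnames = list(LETTERS[1:7], paste0("c", 1:20)))
  pd <- phangorn::phyDat(m + 2L, type = "USER", levels = 1:3)
  costs01 <- state_cost_matrix()
  expect_equal(sankoff_score(tree, character_matrix(m), costs01),
               as.numeric(phangorn::parsimony(tree, pd, method = "sankoff",
                                              cost = costs01)))
})

test_that("Sankoff score is invariant to rooting and linear in the costs", {
  set.seed(31)
  tree <- ape::rtree(6, tip.label = LETTERS[1:6])
  m <- matrix(sample(c(-1L, 0L, 1L), 6 * 10, replace = TRUE), 6, 10,
              dimnames = list(LETTERS[1:6], paste0("c", 1:10)))
  data <- character_matrix(m)
  s <- sankoff_score(tree, data)
  expect_equal(sankoff_score(ape::unroot(tree), data), s)
  for (out in c("B", "E")) {
    expect_equal(sankoff_score(ape::root(ape::unroot(tree), outgroup = out,
                                         resolve.root = TRUE), data), s)
  }
  perm <- data[sample(rownames(data)), ]
  expect_equal(sankoff_score(tree, character_matrix(perm)), s)
  half <- state_cost_matrix(state_cost_matrix() / 2)
  expect_equal(sankoff_score(tree, data, half), s / 2)
})

test_that("four-taxon NNI search matches the exhaustive three-topology optimum", {
  set.seed(47)
  for (rep in 1:5) {
    m <- matrix(sample(c(-1L, 0L, 1L), 4 * 12, replace = TRUE), 4, 12,
                dimnames = list(c("A", "B", "C", "D"), paste0("c", 1:12)))
    data <- character_matrix(m)
    found <- parsimony_search(data, seed = rep)
    all_tops <- phangorn::allTrees(4, rooted = FALSE, tip.label = c("A", "B", "C", "D"))
    best <- min(vapply(all_tops, sankoff_score, 0, data = data))
    expect_equal(found$score, best)
    start <- fingerprintr:::start_tree(data)
    expect_lte(found$score, sankoff_score(start, data))
  }
})

test_that("a planted lineage with clean edge changes is recovered exactly", {
  true_tree <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  base <- setNames(rep(0L, 120), sprintf("pw%03d", 1:120))
  data <- make_lineage(true_tree, base, flips_per_edge = 12, seed = 61)
  found <- parsimony_search(data, seed = 1)
  rf <- phangorn::RF.dist(ape::unroot(true_tree), found$tree)
  expect_equal(rf, 0)
})

test_that("a constant character never changes the selected topology", {
  true_tree <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  base <- setNames(rep(0L, 80), sprintf("pw%03d", 1:80))
  data <- make_lineage(true_tree, base, flips_per_edge = 10, seed = 71)
  with_const <- character_matrix(cbind(data, const = rep(1L, nrow(data))))
  t1 <- parsimony_search(data, seed = 2)
  t2 <- parsimony_search(with_const, seed = 2)
  expect_equal(phangorn::RF.dist(t1$tree, t2$tree), 0)
  expect_equal(t2$score, t1$score)  # constant character adds zero cost
})

test_that("bootstrap supports are 1 on conflict-free data and reproducible", {
  # perfectly compatible characters: blocks marking each non-trivial clade
  clades <- list(c("A", "B"), c("C", "D"), c("E", "F"), c("C", "D", "E", "F"))
  taxa <- c("A", "B", "C", "D", "E", "F")
  data <- character_matrix(do.call(cbind, lapply(clades, function(cl) {
    matrix(rep(ifelse(taxa %in% cl, 1L, -1L), 10), ncol = 10,
           dimnames = list(taxa, NULL))
  })))
  colnames(data) <- sprintf("pw%03d", seq_len(ncol(data)))
  bs1 <- bootstrap_support(data, n_reps = 20, seed = 5)
  expect_true(all(bs1$supports >= 0 & bs1$supports <= 1))
  # internal (non-root) edges of a clean lineage are fully supported
  expect_true(all(bs1$supports[-1] >= 0.95))
  expect_equal(phangorn::RF.dist(
    bs1$tree, ape::unroot(ape::read.tree(text = "((A,B),((C,D),(E,F)));"))), 0)
  bs2 <- bootstrap_support(data, n_reps = 20, seed = 5)
  expect_identical(bs2$supports, bs1$supports)
  expect_equal(phangorn::RF.dist(bs1$tree, bs2$tree), 0)
})

test_that("trees round-trip through newick with supports as node labels", {
  data <- make_lineage(ape::read.tree(text = "((A,B),((C,D),(E,F)));"),
                       setNames(rep(0L, 60), sprintf("pw%03d", 1:60)),
                       flips_per_edge = 8, seed = 91)
  bs <- bootstrap_support(data, n_reps = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_lineage_tree(bs, path)
  back <- read_lineage_tree(path)
  expect_setequal(back$tip.label, rownames(data))
  expect_equal(phangorn::RF.dist(back, bs$tree), 0)
})
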
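#' Ternary state cost matrix
#'
#' Transition cost between fingerprint states for parsimony. The default is
#' the absolute difference between scores, `cost(a, b) = |a - b|`, so a
#' change from underexpressed (-1) to overexpressed (+1) costs twice a
#' change to or from the intermediate state. Must have a zero diagonal, be
#' symmetric and satisfy the triangle inequality.
#'
#' @param costs Optional 3x3 numeric matrix over states (-1, 0, 1).
#' @return A validated cost matrix with dimnames `c("-1","0","1")`.
#' @export
state_cost_matrix <- function(costs = NULL) {
  states <- c(-1, 0, 1)
  if (is.null(costs)) costs <- abs(outer(states, states, "-"))
  costs <- as.matrix(costs)
  if (!identical(dim(costs), c(3L, 3L))) abort("cost matrix must be 3x3")
  if (any(diag(costs) != 0)) abort("cost matrix must have a zero diagonal")
  if (any(costs != t(costs))) abort("cost matrix must be symmetric")
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    if (costs[i, j] > costs[i, k] + costs[k, j] + 1e-12) {
      abort("cost matrix violates the triangle inequality")
    }
  }
  dimnames(costs) <- list(c("-1", "0", "1"), c("-1", "0", "1"))
  costs
}

#' Character matrix of consensus fingerprints per taxon
#'
#' @param characters Taxa-by-pathways matrix with entries in -1/0/1 and
#'   unique taxon rownames; `NA` (unmeasured) is treated as state 0,
#'   consistent with fingerprint semantics.
#' @return A validated `character_matrix`.
#' @export
character_matrix <- function(characters) {
  m <- as.matrix(characters)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    abort("taxa must have unique rownames")
  }
  if (nrow(m) < 3L) abort("need >= 3 taxa")
  m[is.na(m)] <- 0
  if (!all(m %in% c(-1, 0, 1))) abort("character states must be in {-1, 0, 1}")
  storage.mode(m) <- "integer"
  structure(m, class = c("character_matrix", "matrix", "array"))
}

#' Sankoff parsimony score
#'
#' Exact minimum total substitution cost of a character matrix on a tree,
#' computed per character by the Sankoff dynamic program: each node carries
#' the minimum subtree cost conditional on its state; a parent accumulates
#' `min_t(cost(s, t) + S_child(t))` over its children, and the tree cost is
#' the minimum over root states. The score is invariant to the position of
#' the root because the cost matrix is symmetric.
#'
#' @param tree An `ape::phylo` tree whose tip labels equal the taxa.
#' @param data A `character_matrix` (taxa x characters).
#' @param costs A state cost matrix from [state_cost_matrix()].
#' @return Total parsimony cost (numeric scalar).
#' @export
sankoff_score <- function(tree, data, costs = state_cost_matrix()) {
  data <- character_matrix(data)
  if (!setequal(tree$tip.label, rownames(data))) {
    abort("tree tip labels do not match the character matrix taxa")
  }
  costs <- state_cost_matrix(costs)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  nchar <- ncol(data)
  obs <- data[tr$tip.label, , drop = FALSE] + 2L  # state index 1..3
  S <- array(0, dim = c(3L, nchar, ntip + nnode))
  for (i in seq_len(ntip)) {
    m <- matrix(Inf, 3L, nchar)
    m[cbind(obs[i, ], seq_len(nchar))] <- 0
    S[, , i] <- m
  }
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    ch <- S[, , child]
    if (nchar == 1L) ch <- matrix(ch, nrow = 3L)
    contrib <- matrix(0, 3L, nchar)
    for (s in 1:3) {
      contrib[s, ] <- pmin(costs[s, 1] + ch[1, ], costs[s, 2] + ch[2, ],
                           costs[s, 3] + ch[3, ])
    }
    S[, , parent] <- S[, , parent] + contrib
  }
  root <- ntip + 1L
  rootS <- S[, , root]
  if (nchar == 1L) rootS <- matrix(rootS, nrow = 3L)
  sum(apply(rootS, 2L, min))
}

start_tree <- function(data) {
  n <- nrow(data)
  d <- matrix(0, n, n, dimnames = list(rownames(data), rownames(data)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(abs(data[i, ] - data[j, ])) / (2 * ncol(data))
  }
  tr <- ape::nj(stats::as.dist(d))
  ape::unroot(tr)
}

#' Heuristic maximum-parsimony tree search by NNI
#'
#' Hill-climbs from a neighbor-joining start tree (built on the normalized
#' Manhattan distances between the taxa's fingerprint rows), repeatedly
#' evaluating every nearest-neighbor-interchange rearrangement and accepting
#' the first strict improvement in Sankoff cost, until no rearrangement
#' improves the score. Deterministic given the seed and a fixed edge
#' enumeration order.
#'
#' @param data A `character_matrix` with >= 4 taxa.
#' @param costs A state cost matrix.
#' @param seed Integer seed.
#' @return A `parsimony_tree`: list with `tree` (unrooted `phylo`), `score`,
#'   and `supports` (`NULL` until [bootstrap_support()]).
#' @export
parsimony_search <- function(data, costs = state_cost_matrix(), seed = 1) {
  data <- character_matrix(data)
  if (nrow(data) < 4L) abort("NNI search needs >= 4 taxa")
  costs <- state_cost_matrix(costs)
  res <- withr::with_seed(seed, {
    tree <- start_tree(data)
    score <- sankoff_score(tree, data, costs)
    repeat {
      improved <- FALSE
      neighbors <- phangorn::nni(tree)
      # index through `[[` so compressed multiPhylo tip labels are restored
      for (k in seq_along(neighbors)) {
        cand <- neighbors[[k]]
        s <- sankoff_score(cand, data, costs)
        if (s < score) {
          tree <- cand
          score <- s
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    list(tree = tree, score = score)
  })
  structure(list(tree = res$tree, score = res$score, supports = NULL),
            class = "parsimony_tree")
}

#' @export
print.parsimony_tree <- function(x, ...) {
  cat(sprintf("<parsimony_tree> %d taxa, parsimony score %g%s\n",
              length(x$tree$tip.label), x$score,
              if (is.null(x$supports)) "" else
                sprintf(", bootstrap over %d replicates", attr(x$supports, "n_reps"))))
  invisible(x)
}

#' Nonparametric bootstrap supports for a parsimony tree
#'
#' Resamples the characters (pathway columns) with replacement, re-runs the
#' parsimony search on each replicate, and reports for every internal edge
#' of the point-estimate tree the fraction of replicate trees containing the
#' same bipartition of taxa. Supports are attached as node labels.
#'
#' @param data A `character_matrix` with >= 4 taxa.
#' @param costs A state cost matrix.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return A `parsimony_tree` whose `supports` field holds per-internal-node
#'   support values in `[0, 1]` and whose tree carries them as node labels.
#' @export
bootstrap_support <- function(data, costs = state_cost_matrix(), n_reps = 100,
                              seed = 1) {
  data <- character_matrix(data)
  if (n_reps < 1) abort("n_reps must be >= 1")
  point <- parsimony_search(data, costs, seed = seed)
  reps <- withr::with_seed(seed + 1L, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample(ncol(data), replace = TRUE)
      boot <- data[, idx, drop = FALSE]
      colnames(boot) <- paste0("c", seq_len(ncol(boot)))
      parsimony_search(character_matrix(boot), costs, seed = seed + r)$tree
    })
  })
  counts <- ape::prop.clades(point$tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- counts / n_reps
  attr(supports, "n_reps") <- n_reps
  tree <- point$tree
  tree$node.label <- formatC(supports, format = "g")
  structure(list(tree = tree, score = point$score, supports = supports),
            class = "parsimony_tree")
}

#' Write / read lineage trees as Newick
#'
#' Bootstrap supports, when present, travel as internal node labels.
#'
#' @param x A `parsimony_tree` or `ape::phylo`.
#' @param path File path.
#' @return The path (writer) or an `ape::phylo` (reader).
#' @export
write_lineage_tree <- function(x, path) {
  tree <- if (inherits(x, "parsimony_tree")) x$tree else x
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_lineage_tree
#' @export
read_lineage_tree <- function(path) ape::read.tree(path)
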
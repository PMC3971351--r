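# Independent oracles used across tests. Each is a deliberately naive
# implementation kept separate from the package code paths it checks.

# Mean squared rank by explicit loops.
brute_pathway_score <- function(expr_col, members, min_genes) {
  r <- rank(expr_col)
  hits <- names(expr_col)[names(expr_col) %in% members]
  if (length(hits) < min_genes) return(NA_real_)
  total <- 0
  for (g in hits) total <- total + r[[g]]^2
  total / length(hits)
}

# Average interpolated precision by direct enumeration of the ranked list.
brute_ap <- function(rel) {
  hits <- which(rel)
  if (length(hits) == 0) return(NA_real_)
  ap <- 0
  for (h in seq_along(hits)) {
    # interpolated precision at this recall point: best precision at or
    # beyond it down the list
    best <- 0
    for (j in hits[hits >= hits[h]]) {
      best <- max(best, sum(rel[1:j]) / j)
    }
    ap <- ap + best
  }
  ap / length(hits)
}

# Sankoff cost by exhaustive enumeration over all internal-state labelings.
brute_sankoff <- function(tree, data, costs) {
  states <- c(-1L, 0L, 1L)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  obs <- data[tree$tip.label, , drop = FALSE]
  grid <- expand.grid(rep(list(states), nnode))
  total <- 0
  for (ch in seq_len(ncol(obs))) {
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      lab <- c(obs[, ch], as.integer(grid[g, ]))
      cost <- 0
      for (e in seq_len(nrow(tree$edge))) {
        a <- lab[tree$edge[e, 1]]
        b <- lab[tree$edge[e, 2]]
        cost <- cost + costs[as.character(a), as.character(b)]
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# Exact 1-D 2-means by explicit evaluation of every split of the sorted data.
brute_two_means <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  best <- Inf
  cut <- NA_real_
  for (i in 1:(n - 1)) {
    if (s[i] == s[i + 1]) next
    lo <- s[1:i]
    hi <- s[(i + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best - 1e-12) {
      best <- wss
      cut <- s[i]
    }
  }
  cut
}

# Two-group log-rank statistic from the hypergeometric tally at each
# distinct event time.
brute_logrank <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Small reusable gene-set collection fixture.
toy_collection <- function() {
  geneset_collection(
    list(alpha = c("g1", "g2", "g3"),
         beta = c("g2", "g3", "g4", "g5"),
         gamma = c("g6", "g7", "g8", "g9", "g10")),
    source = c("KEGG", "KEGG", "custom"), species = "human"
  )
}

# Default synthetic corpus fingerprinted once and shared across test files.
.test_cache <- new.env(parent = emptyenv())
test_corpus_fingerprints <- function() {
  if (is.null(.test_cache$fc)) {
    corp <- make_corpus(corpus_design(seed = 20260921))
    .test_cache$corp <- corp
    .test_cache$fc <- fingerprint_corpus(corp)
  }
  list(corp = .test_cache$corp, fc = .test_cache$fc)
}
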
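#' Ternary fingerprints from POE
#'
#' Applies the ternary threshold `T` to signed POE values: a pathway scores
#' `+1` when `POE >= T` (significantly high), `-1` when `POE <= -T`
#' (significantly low) and `0` otherwise; both boundaries are inclusive.
#' The default `T = 0.001` is deliberately permissive: at the pathway level
#' the coordinated effect of many genes makes even subtle shifts in the
#' score informative, and larger thresholds discard them. Pathways with
#' absent POE (no background fit or too few represented genes) are set to 0
#' and tracked in the `unmeasured` matrix so they can be excluded from
#' distances if desired.
#'
#' @param poe A `poe_matrix`, or a plain numeric vector/matrix of POE values.
#' @param threshold Ternary threshold in (0, 1); default 0.001.
#' @return A `fingerprint_matrix`: integer pathways-by-samples matrix with
#'   entries in {-1, 0, 1}, plus an `unmeasured` logical matrix and the
#'   collection id when available.
#' @export
ternarize <- function(poe, threshold = 0.001) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (inherits(poe, "poe_matrix")) {
    vals <- poe$poe
    meta <- poe[c("platform", "species", "collection_id")]
  } else {
    vals <- if (is.matrix(poe)) poe else
      matrix(poe, ncol = 1, dimnames = list(names(poe), "S1"))
    meta <- list(platform = NA_character_, species = NA_character_,
                 collection_id = NA_character_)
  }
  unmeasured <- is.na(vals)
  f <- matrix(0L, nrow = nrow(vals), ncol = ncol(vals), dimnames = dimnames(vals))
  f[!unmeasured & vals >= threshold] <- 1L
  f[!unmeasured & vals <= -threshold] <- -1L
  structure(c(list(scores = f, unmeasured = unmeasured, threshold = threshold),
              meta),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  tab <- table(factor(x$scores, levels = c(-1, 0, 1)))
  cat(sprintf("<fingerprint_matrix> %d pathways x %d samples (T=%g): -1:%d 0:%d +1:%d\n",
              nrow(x$scores), ncol(x$scores), x$threshold,
              tab[["-1"]], tab[["0"]], tab[["1"]]))
  invisible(x)
}

#' Expression-to-fingerprint pipeline for one platform
#'
#' Convenience wrapper chaining [rank_transform()], [pathway_scores()],
#' [poe_transform()] and [ternarize()].
#'
#' @param em An `expression_matrix`.
#' @param col A `geneset_collection`.
#' @param bg A `platform_background` for `em`'s platform.
#' @param threshold Ternary threshold.
#' @param min_genes Passed to [pathway_scores()].
#' @return A `fingerprint_matrix`.
#' @export
fingerprint_expression <- function(em, col, bg, threshold = 0.001, min_genes = 3) {
  scores <- pathway_scores(rank_transform(em), col, min_genes = min_genes)
  ternarize(poe_transform(scores, bg), threshold = threshold)
}

as_score_matrix <- function(x) {
  if (inherits(x, "fingerprint_matrix")) x$scores
  else if (is.matrix(x)) x
  else matrix(x, ncol = 1, dimnames = list(names(x), NULL))
}

#' Consensus fingerprint of a group of samples
#'
#' Per pathway, let `mu` be the mean ternary score across the group; the
#' consensus is `+1` when `mu > t`, `-1` when `mu < -t`, else `0` (strict
#' inequalities). Non-zero consensus entries are the pathways consistently
#' and significantly expressed across the group — a discrete functional
#' identity for the phenotype.
#'
#' @param prints A `fingerprint_matrix` or ternary matrix (pathways x samples).
#' @param t Consensus threshold in (0, 1].
#' @return A `consensus_fingerprint`: named ternary vector plus `t` and the
#'   number of contributing samples.
#' @export
consensus_fingerprint <- function(prints, t) {
  if (t <= 0 || t > 1) abort("consensus threshold t must be in (0, 1]")
  m <- as_score_matrix(prints)
  if (ncol(m) < 1L) abort("need at least one fingerprint")
  mu <- rowMeans(m)
  cons <- integer(length(mu))
  cons[mu > t] <- 1L
  cons[mu < -t] <- -1L
  names(cons) <- rownames(m)
  structure(list(scores = cons, t = t, n_samples = ncol(m)),
            class = "consensus_fingerprint")
}

#' @export
print.consensus_fingerprint <- function(x, ...) {
  cat(sprintf("<consensus_fingerprint> %d pathways (t=%g, n=%d): %d non-zero\n",
              length(x$scores), x$t, x$n_samples, sum(x$scores != 0L)))
  invisible(x)
}

manhattan_ternary <- function(a, b) sum(abs(a - b)) / (2 * length(a))

#' Normalized Manhattan distance between fingerprints
#'
#' `d(a, b) = sum(|a_i - b_i|) / (2N)` over the `N` pathways compared, so the
#' distance scales from 0 (all pathway scores matched) to 1 (all mismatched,
#' i.e. +1 versus -1 everywhere).
#'
#' @param a,b Ternary vectors of equal length (or single-column fingerprints).
#' @return A one-row tibble with `distance` and `n_compared`.
#' @export
fingerprint_distance <- function(a, b) {
  a <- as_ternary_vector(a)
  b <- as_ternary_vector(b)
  if (length(a) != length(b)) abort("fingerprints have different lengths")
  tibble(distance = manhattan_ternary(a, b), n_compared = length(a))
}

as_ternary_vector <- function(x) {
  if (inherits(x, "consensus_fingerprint")) return(x$scores)
  if (inherits(x, "fingerprint_matrix")) x <- x$scores
  if (is.matrix(x)) {
    if (ncol(x) != 1L) abort("expected a single fingerprint vector")
    return(drop(x))
  }
  x
}

#' Distance from a consensus fingerprint
#'
#' Restricted to the pathways where the consensus is non-zero, so only
#' differences in the consistently expressed pathways that define the
#' consensus are counted.
#'
#' @param cons A `consensus_fingerprint` with at least one non-zero entry.
#' @param v A ternary vector or single-column fingerprint on the same
#'   pathway coordinates.
#' @return A one-row tibble with `distance` and `n_compared`.
#' @export
consensus_distance <- function(cons, v) {
  stopifnot(inherits(cons, "consensus_fingerprint"))
  nz <- which(cons$scores != 0L)
  if (length(nz) == 0L) abort("all-zero consensus: no informative pathways")
  v <- as_ternary_vector(v)
  if (length(v) != length(cons$scores)) abort("fingerprint length mismatch")
  tibble(distance = manhattan_ternary(cons$scores[nz], v[nz]),
         n_compared = length(nz))
}

#' Retrieval significance from the distribution of corpus distances
#'
#' Models the distances of the (overwhelmingly) non-matched corpus samples
#' from a consensus as normal, with the mean estimated by the median and the
#' SD by `IQR / 1.349` — both robust to the small contaminating population
#' of true matches at low distance. The p-value of a distance `d` is the
#' lower tail `Phi((d - m) / s)`: a small distance is a significant match.
#'
#' @param distances Numeric vector of corpus distances (>= 20, non-zero IQR).
#' @param d Distances to score; defaults to `distances` itself.
#' @return Numeric vector of p-values, monotone non-decreasing in `d`.
#' @export
distance_pvalue <- function(distances, d = distances) {
  if (length(distances) < 20L) abort("need >= 20 corpus distances")
  s <- IQR(distances) / 1.349
  if (s == 0) abort("zero IQR: distance distribution is degenerate")
  pnorm((d - median(distances)) / s)
}

#' Rank a fingerprint corpus by similarity to a consensus
#'
#' Orders corpus samples by their consensus-restricted distance, ties broken
#' by sample id for determinism, and attaches retrieval p-values when the
#' corpus is large enough to estimate the null.
#'
#' @param cons A `consensus_fingerprint`.
#' @param corpus A `fingerprint_matrix` (or ternary matrix) on the same
#'   pathway coordinates.
#' @return A tibble `(sample, distance, p_value)` in ascending distance.
#' @export
rank_corpus <- function(cons, corpus) {
  m <- as_score_matrix(corpus)
  if (ncol(m) == 0L) abort("empty corpus")
  if (nrow(m) != length(cons$scores)) abort("corpus not aligned to the consensus collection")
  nz <- which(cons$scores != 0L)
  if (length(nz) == 0L) abort("all-zero consensus: no informative pathways")
  d <- colSums(abs(m[nz, , drop = FALSE] - cons$scores[nz])) / (2 * length(nz))
  p <- if (length(d) >= 20L && IQR(d) > 0) distance_pvalue(d) else rep(NA_real_, length(d))
  out <- tibble(sample = colnames(m) %||% as.character(seq_along(d)),
                distance = unname(d), p_value = unname(p))
  arrange(out, .data$distance, .data$sample)
}

#' Read / write ternary fingerprint matrices as TSV
#'
#' Pathways in rows, samples in columns, entries -1/0/1; unmeasured pathways
#' are written as 0 (they are tracked separately in memory only).
#'
#' @param fp A `fingerprint_matrix` (or plain ternary matrix).
#' @param path File path.
#' @return The path (writer) or a `fingerprint_matrix` (reader).
#' @export
write_fingerprints <- function(fp, path) {
  write_matrix_tsv(as_score_matrix(fp), path, id_col = "pathway")
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  m <- read_matrix_tsv(path)
  storage.mode(m) <- "integer"
  structure(list(scores = m, unmeasured = is.na(m),
                 threshold = NA_real_, platform = NA_character_,
                 species = NA_character_, collection_id = NA_character_),
            class = "fingerprint_matrix")
}

#' Heatmap of a ternary fingerprint matrix
#' @param object A `fingerprint_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot (blue -1, white 0, red +1).
#' @export
autoplot.fingerprint_matrix <- function(object, ...) {
  df <- as_tibble(as.table(object$scores), .name_repair = ~ c("pathway", "sample", "score"))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$pathway,
                                   fill = factor(.data$score, levels = c(-1, 0, 1)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`-1` = "#2166AC", `0` = "white", `1` = "#B2182B"),
                               name = "score", drop = FALSE) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
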
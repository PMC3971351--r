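#' Expression matrices
#'
#' A genes-by-samples matrix of one-channel expression values for a single
#' platform and species, after any probe-to-gene collapse. Values must be
#' finite; any within-array normalization is acceptable upstream because all
#' downstream scoring is rank-based.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames).
#' @param platform Platform tag (e.g. an array identifier).
#' @param species Species tag.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, platform, species) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) abort("need >= 1 gene and >= 1 sample")
  if (is.null(rownames(values))) abort("rows must be named by gene id")
  if (anyDuplicated(rownames(values))) abort("gene ids must be unique")
  if (is.null(colnames(values))) colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (!all(is.finite(values))) abort("expression values must all be finite")
  structure(list(values = values, platform = platform, species = species),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, platform '%s' (%s)\n",
              nrow(x$values), ncol(x$values), x$platform, x$species))
  invisible(x)
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV: header row of sample ids, first column gene ids. GCT 1.2 (detected by
#' a `.gct` extension or a leading `#1.2` line): the two header lines and the
#' Description column are skipped.
#'
#' @param path Input path.
#' @inheritParams expression_matrix
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, platform, species) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  is_gct <- grepl("\\.gct$", path, ignore.case = TRUE) || startsWith(first, "#1.2")
  if (is_gct) {
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE)
    genes <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             comment.char = "#")
    genes <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
  }
  rownames(vals) <- genes
  expression_matrix(vals, platform = platform, species = species)
}

#' Write an expression matrix as TSV
#' @param em An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  write_matrix_tsv(em$values, path, id_col = "gene_id")
}

write_matrix_tsv <- function(m, path, id_col = "id", header_lines = character()) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Collapse probe-level values to gene level
#'
#' Probes mapping to the same gene are merged by taking the arithmetic mean of
#' their intensities per sample; probes without an annotation are dropped.
#'
#' @param probe_matrix Probes-by-samples numeric matrix with probe rownames.
#' @param annotation Probe-to-gene map: either a named character vector
#'   (names = probe ids, values = gene ids) or a two-column data frame
#'   (probe, gene).
#' @param platform,species Tags for the resulting matrix.
#' @return An `expression_matrix` with one row per mapped gene.
#' @export
collapse_probes <- function(probe_matrix, annotation, platform, species) {
  probe_matrix <- as.matrix(probe_matrix)
  if (is.data.frame(annotation)) {
    annotation <- setNames(as.character(annotation[[2]]), as.character(annotation[[1]]))
  }
  gene <- annotation[rownames(probe_matrix)]
  keep <- !is.na(gene)
  if (!any(keep)) abort("no probe in the matrix is covered by the annotation")
  m <- probe_matrix[keep, , drop = FALSE]
  g <- gene[keep]
  sums <- rowsum(m, group = g)
  counts <- as.vector(table(g)[rownames(sums)])
  expression_matrix(sums / counts, platform = platform, species = species)
}

#' Rank-transform an expression matrix
#'
#' Genes are ranked per sample in ascending order of expression, 1 = lowest,
#' `T` = highest where `T` is the total number of genes on the array. Ties
#' take the average of the tied rank positions, which keeps the per-column
#' rank sum at exactly `T(T+1)/2`.
#'
#' @param em An `expression_matrix`.
#' @return An object of class `rank_matrix` with fields `ranks`,
#'   `total_genes`, `platform`, `species`.
#' @export
rank_transform <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  ranks <- apply(em$values, 2L, rank)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1L,
                                           dimnames = dimnames(em$values))
  rownames(ranks) <- rownames(em$values)
  structure(list(ranks = ranks, total_genes = nrow(ranks),
                 platform = em$platform, species = em$species),
            class = "rank_matrix")
}

#' Mean-squared-rank pathway expression scores
#'
#' For a pathway represented on the array by `n` member genes with
#' within-sample ranks `R_1..R_n`, the pathway expression score is the mean
#' squared rank `(1/n) * sum(R_i^2)`. Because it depends on the data only
#' through ranks, the score is invariant under any strictly monotone
#' transform of a sample's expression values, which is what makes it
#' comparable across platforms with different dynamic ranges.
#'
#' Pathways with fewer than `min_genes` members present among the matrix rows
#' are marked missing (`NA`) rather than scored; missing scores propagate as
#' "unmeasured" through the POE and ternary steps and are never imputed.
#'
#' @param rm A `rank_matrix`.
#' @param col A `geneset_collection`; its set order fixes the row order.
#' @param min_genes Minimum represented members for a score (default 3;
#'   set 1 to score every represented pathway).
#' @return A `pathway_score_matrix`: pathways-by-samples scores with `NA`
#'   where unmeasured, plus `n_genes` (represented member counts), the
#'   platform tag and the collection hash.
#' @export
pathway_scores <- function(rm, col, min_genes = 3) {
  stopifnot(inherits(rm, "rank_matrix"), inherits(col, "geneset_collection"))
  if (min_genes < 1) abort("min_genes must be >= 1")
  if (length(col) == 0L) abort("empty gene-set collection")
  gene_ids <- rownames(rm$ranks)
  sq <- rm$ranks^2
  scores <- matrix(NA_real_, nrow = length(col), ncol = ncol(rm$ranks),
                   dimnames = list(names(col$sets), colnames(rm$ranks)))
  n_genes <- integer(length(col))
  names(n_genes) <- names(col$sets)
  for (i in seq_along(col$sets)) {
    idx <- which(gene_ids %in% col$sets[[i]])
    n_genes[i] <- length(idx)
    if (length(idx) >= min_genes) {
      scores[i, ] <- colMeans(sq[idx, , drop = FALSE])
    }
  }
  structure(list(scores = scores, n_genes = n_genes, min_genes = min_genes,
                 platform = rm$platform, species = rm$species,
                 collection_id = collection_hash(col)),
            class = "pathway_score_matrix")
}

#' @export
print.pathway_score_matrix <- function(x, ...) {
  cat(sprintf("<pathway_score_matrix> %d pathways x %d samples, platform '%s' (%d unmeasured)\n",
              nrow(x$scores), ncol(x$scores), x$platform,
              sum(is.na(x$scores[, 1]))))
  invisible(x)
}

#' Stable identifier of a collection's content and order
#'
#' Hash of the set names, set order and memberships. Backgrounds store it and
#' POE refuses to run against a collection with a different hash, so a
#' fingerprint can never be silently misaligned with its null model.
#'
#' @param col A `geneset_collection`.
#' @return A character scalar.
#' @export
collection_hash <- function(col) {
  hash(list(names(col$sets), unname(col$sets)))
}
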
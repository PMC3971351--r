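#' Gene-set collections
#'
#' A `geneset_collection` is an ordered, named list of gene sets (character
#' vectors of gene identifiers) with per-set source labels and a species tag.
#' The order of the sets is stable and defines the coordinate order of every
#' fingerprint computed against the collection. Gene identifiers are opaque
#' strings; no species-specific validation is applied.
#'
#' @param sets Named list of character vectors (gene identifiers). Duplicate
#'   members within a set are removed silently; empty sets and duplicate or
#'   empty set names are errors.
#' @param source Character vector of per-set provenance labels (e.g.
#'   "Reactome", "KEGG", "static", "custom"), recycled if length 1.
#' @param species Species tag for the whole collection.
#' @param version Free-text provenance string.
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, source = "custom", species = "human",
                               version = "") {
  if (length(sets) == 0L) abort("a collection needs at least one gene set")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) abort("every gene set needs a non-empty name")
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene-set name(s): ", paste(unique(dup), collapse = ", ")))
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) abort("gene sets must be non-empty")
  source <- rep_len(as.character(source), length(sets))
  names(source) <- nm
  structure(
    list(sets = sets, source = source, species = species, version = version),
    class = "geneset_collection"
  )
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf(
    "<geneset_collection> %d sets, species '%s', %d distinct genes\n",
    length(x$sets), x$species, length(unique(unlist(x$sets, use.names = FALSE)))
  ))
  invisible(x)
}

#' Set sizes of a collection
#' @param col A `geneset_collection`.
#' @return Named integer vector of member counts.
#' @export
set_sizes <- function(col) lengths(col$sets)

#' Read a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. The description column is stored as
#' the source label ("custom" when empty). Member duplicates within a line
#' are removed silently. Round-trips losslessly through [write_gmt()].
#'
#' @param path Path to a GMT file.
#' @inheritParams geneset_collection
#' @return A `geneset_collection`.
#' @export
read_gmt <- function(path, species = "human", version = "") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene-set name(s) in GMT: ", paste(unique(dup), collapse = ", ")))
  }
  src <- vapply(fields, `[[`, "", 2L)
  src[!nzchar(src)] <- "custom"
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  geneset_collection(sets, source = src, species = species, version = version)
}

#' Write a GMT file
#' @param col A `geneset_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(col, path) {
  lines <- vapply(seq_along(col$sets), function(i) {
    paste(c(names(col$sets)[i], col$source[[i]], col$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Homology maps
#'
#' A `homology_map` carries a one-to-one-or-many mapping from source-species
#' gene ids to target-species gene ids. Every key maps to exactly one target;
#' many keys may share a target.
#'
#' @param pairs Named character vector: `names(pairs)` are source-species ids,
#'   values are target-species ids.
#' @param source_species,target_species Species tags.
#' @return An object of class `homology_map`.
#' @export
homology_map <- function(pairs, source_species, target_species) {
  if (is.null(names(pairs)) || any(!nzchar(names(pairs)))) {
    abort("homology pairs must be a named character vector")
  }
  if (anyDuplicated(names(pairs))) abort("each source gene may map to only one target")
  structure(
    list(pairs = pairs, source_species = source_species,
         target_species = target_species),
    class = "homology_map"
  )
}

#' Read a two-column homology table
#'
#' Headerless TSV, column 1 = source-species gene id, column 2 = target id.
#'
#' @param path Path to the TSV.
#' @inheritParams homology_map
#' @return A `homology_map`.
#' @export
read_homology_map <- function(path, source_species, target_species) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) abort("homology table needs two columns")
  homology_map(setNames(tab[[2]], tab[[1]]), source_species, target_species)
}

#' Map a collection to another species by homology
#'
#' Each member gene is replaced by its homolog when one exists and dropped
#' otherwise; duplicate targets arising from many-to-one homology collapse to
#' one; sets left with fewer than `min_size` members are removed. The species
#' tag is updated to the map's target species.
#'
#' @param col A `geneset_collection`.
#' @param hmap A `homology_map` whose source species matches `col$species`.
#' @param min_size Minimum surviving set size (default 5).
#' @return A mapped `geneset_collection`.
#' @export
map_collection <- function(col, hmap, min_size = 5) {
  stopifnot(inherits(col, "geneset_collection"), inherits(hmap, "homology_map"))
  if (!identical(hmap$source_species, col$species)) {
    abort(sprintf("homology map is %s -> %s but collection species is '%s'",
                  hmap$source_species, hmap$target_species, col$species))
  }
  mapped <- lapply(col$sets, function(m) {
    hit <- hmap$pairs[m]
    unique(unname(hit[!is.na(hit)]))
  })
  keep <- lengths(mapped) >= min_size
  if (!any(keep)) abort("no gene set survives homology mapping at this min_size")
  geneset_collection(mapped[keep], source = col$source[keep],
                     species = hmap$target_species, version = col$version)
}

#' Randomly constructed gene sets matched for size
#'
#' Builds a comparator collection with the same number of sets and the exact
#' same multiset of set sizes, each set sampled without replacement from the
#' union of all genes in the original collection. Used as the null comparator
#' in benchmarks: any retrieval skill it shows reflects gene coverage alone,
#' not pathway structure.
#'
#' @param col A `geneset_collection`.
#' @param seed Integer seed; mandatory, reproducibility is part of the contract.
#' @return A `geneset_collection` with sets named `random_<i>`.
#' @export
random_genesets <- function(col, seed) {
  if (missing(seed) || is.null(seed)) abort("random_genesets requires an explicit seed")
  universe <- unique(unlist(col$sets, use.names = FALSE))
  sizes <- lengths(col$sets)
  if (max(sizes) > length(universe)) {
    abort("largest set exceeds the size of the gene universe")
  }
  sets <- withr::with_seed(seed, lapply(sizes, function(k) sample(universe, k)))
  names(sets) <- paste0("random_", seq_along(sets))
  geneset_collection(sets, source = "random", species = col$species,
                     version = paste0("randomized from: ", col$version))
}

#' Summarize a collection by source
#'
#' @param col A non-empty `geneset_collection`.
#' @return A list with `by_source`, a tibble of per-source counts and size
#'   statistics (plus an "All" row), and `overlap`, a symmetric source-by-source
#'   matrix of shared distinct-gene counts whose diagonal holds per-source
#'   distinct-gene totals.
#' @export
collection_summary <- function(col) {
  stopifnot(inherits(col, "geneset_collection"))
  sizes <- lengths(col$sets)
  src <- col$source
  src_levels <- unique(src)
  genes_by_src <- lapply(src_levels, function(s) {
    unique(unlist(col$sets[src == s], use.names = FALSE))
  })
  names(genes_by_src) <- src_levels
  row_for <- function(label, idx, genes) {
    tibble(
      source = label, n_sets = length(idx),
      mean_size = mean(sizes[idx]), median_size = median(sizes[idx]),
      min_size = min(sizes[idx]), max_size = max(sizes[idx]),
      total_genes = length(genes)
    )
  }
  by_source <- bind_rows(lapply(src_levels, function(s) {
    row_for(s, which(src == s), genes_by_src[[s]])
  }))
  all_genes <- unique(unlist(col$sets, use.names = FALSE))
  by_source <- bind_rows(by_source, row_for("All", seq_along(sizes), all_genes))
  overlap <- outer(seq_along(src_levels), seq_along(src_levels),
                   Vectorize(function(i, j) {
                     length(intersect(genes_by_src[[i]], genes_by_src[[j]]))
                   }))
  dimnames(overlap) <- list(src_levels, src_levels)
  list(by_source = by_source, overlap = overlap)
}
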
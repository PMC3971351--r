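#' Design of a synthetic multi-platform, multi-species corpus
#'
#' Describes a fully synthetic study: several array platforms with partially
#' overlapping gene coverage, a shared gene-set collection, tissue-like
#' classes that activate chosen pathways up or down, background arrays with
#' no activation (for fitting platform backgrounds), and a second species
#' linked by a homology map. Effect sizes are parameterized on the
#' rank-quantile scale — an `effect_size` of `e` pushes an activated gene's
#' expected within-sample quantile a fraction `e` of the way toward 1 (up)
#' or 0 (down) — so "strong" and "weak" mean the same thing on every
#' platform regardless of its dynamic range.
#'
#' @param n_platforms Number of platforms (one per species, cycled through
#'   `species`).
#' @param genes_per_platform Genes measured on each platform.
#' @param platform_gene_overlap Fraction of each platform's genes drawn from
#'   a core shared by all platforms.
#' @param n_pathways Number of gene sets in the collection.
#' @param pathway_size Length-2 integer range of set sizes.
#' @param n_classes Number of phenotype classes.
#' @param pathways_per_class Distinct pathways activated by each class.
#' @param effect_size Rank-quantile shift of activated member genes, in
#'   `[0, 1]`.
#' @param class_modulation Weak rank-quantile shift applied by each class to
#'   every non-planted pathway, in a class-specific random direction fixed
#'   across platforms and species (default 0.2). Real tissues modulate most
#'   transcriptional programs subtly and consistently, not just a few
#'   strongly; this term reproduces that property, without which permissive
#'   ternary thresholds would have nothing to gain from subtle shifts. Set 0
#'   for strictly sparse activation.
#' @param n_samples_per_class Samples per class per platform.
#' @param n_background Unactivated background arrays per platform.
#' @param species Character vector of species tags; platforms cycle through
#'   it.
#' @param homology_fraction Fraction of non-pathway core genes with a
#'   homolog in the other species (pathway genes are always homologous so
#'   mapped collections keep identical coordinates).
#' @param seed Integer seed; mandatory.
#' @return A validated `corpus_design` list.
#' @export
corpus_design <- function(n_platforms = 2, genes_per_platform = 1000,
                          platform_gene_overlap = 0.8, n_pathways = 50,
                          pathway_size = c(10, 30), n_classes = 4,
                          pathways_per_class = 3, effect_size = 0.8,
                          class_modulation = 0.2,
                          n_samples_per_class = 25, n_background = 100,
                          species = c("human", "mouse"),
                          homology_fraction = 0.9, seed) {
  if (missing(seed) || is.null(seed)) abort("corpus_design requires an explicit seed")
  if (effect_size < 0 || effect_size > 1) abort("effect_size must be in [0, 1]")
  if (class_modulation < 0 || class_modulation > 1) {
    abort("class_modulation must be in [0, 1]")
  }
  fracs <- c(platform_gene_overlap, homology_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must be in [0, 1]")
  if (length(pathway_size) != 2L || pathway_size[1] > pathway_size[2]) {
    abort("pathway_size must be an increasing length-2 range")
  }
  if (n_classes * pathways_per_class > n_pathways) {
    abort("classes need more distinct pathways than the collection holds")
  }
  structure(
    list(n_platforms = n_platforms, genes_per_platform = genes_per_platform,
         platform_gene_overlap = platform_gene_overlap,
         n_pathways = n_pathways, pathway_size = as.integer(pathway_size),
         n_classes = n_classes, pathways_per_class = pathways_per_class,
         effect_size = effect_size, class_modulation = class_modulation,
         n_samples_per_class = n_samples_per_class,
         n_background = n_background, species = species,
         homology_fraction = homology_fraction, seed = as.integer(seed)),
    class = "corpus_design"
  )
}

# Monotone per-platform transforms: rank-based scoring must be blind to them.
platform_transforms <- list(
  function(x) x,
  function(x) exp(x / 3),
  function(x) 100 + 7 * x,
  function(x) sign(x) * abs(x)^1.5
)

#' Generate a synthetic corpus
#'
#' Baseline expression for gene `g` in sample `s` on platform `p` is
#' `f_p(offset_gp + z)`, with `z` standard normal, `offset_gp` a per-gene,
#' per-platform baseline shift and `f_p` a strictly monotone platform
#' transform. Genes of a pathway activated by the sample's class have their
#' normal quantile `u` remapped to `1 - (1-u)(1-e)` (up) or `u(1-e)` (down),
#' moving their expected rank quantile by the design's effect size `e`.
#' Background samples carry no activation. Pathway members are drawn from
#' the cross-platform, cross-species core so every set is measurable
#' everywhere and mapped collections keep identical coordinates.
#'
#' @param design A `corpus_design`.
#' @return A `synthetic_corpus` list: `expression` (list of
#'   `expression_matrix`, one per platform, class samples then background
#'   samples), `collections` (one `geneset_collection` per species),
#'   `homology` (list of `homology_map`s from the first species to each
#'   other species), `truth` (tibble `sample, platform, species, class`;
#'   background samples labeled `"background"`), and `activations` (tibble
#'   `class, pathway, direction`).
#' @export
make_corpus <- function(design) {
  stopifnot(inherits(design, "corpus_design"))
  d <- design
  withr::with_seed(d$seed, {
    n_core <- round(d$platform_gene_overlap * d$genes_per_platform)
    n_specific <- d$genes_per_platform - n_core
    core <- sprintf("g%05d", seq_len(n_core))
    # pathway members come from the orthologous core
    max_size <- d$pathway_size[2]
    if (max_size > n_core) abort("pathway sizes exceed the shared gene core")
    sizes <- sample(seq(d$pathway_size[1], d$pathway_size[2]), d$n_pathways,
                    replace = TRUE)
    sets <- lapply(sizes, function(k) sample(core, k))
    names(sets) <- sprintf("pathway_%03d", seq_len(d$n_pathways))
    col1 <- geneset_collection(sets, source = "synthetic",
                               species = d$species[1], version = "synthetic corpus")
    pathway_genes <- unique(unlist(sets, use.names = FALSE))

    # class activations: disjoint pathway blocks, alternating direction
    classes <- sprintf("class_%d", seq_len(d$n_classes))
    act_idx <- matrix(seq_len(d$n_classes * d$pathways_per_class),
                      nrow = d$pathways_per_class)
    activations <- bind_rows(lapply(seq_len(d$n_classes), function(ci) {
      pw <- names(sets)[act_idx[, ci]]
      tibble(class = classes[ci], pathway = pw,
             direction = rep_len(c(1L, -1L), length(pw)))
    }))
    # weak class-specific modulation of every non-planted pathway, fixed
    # across platforms/species so same-class samples shift consistently
    modulations <- activations
    modulations$effect <- d$effect_size
    if (d$class_modulation > 0) {
      weak <- bind_rows(lapply(seq_len(d$n_classes), function(ci) {
        pw <- setdiff(names(sets), activations$pathway[activations$class == classes[ci]])
        tibble(class = classes[ci], pathway = pw,
               direction = sample(c(1L, -1L), length(pw), replace = TRUE),
               effect = d$class_modulation)
      }))
      modulations <- bind_rows(modulations, weak)
    }

    plat_species <- rep_len(d$species, d$n_platforms)
    expression <- vector("list", d$n_platforms)
    truth_rows <- vector("list", d$n_platforms)
    homology <- list()
    collections <- list()
    collections[[d$species[1]]] <- col1

    # species gene ids: first species uses the master ids, others prefixed
    species_id <- function(sp, genes) {
      if (sp == d$species[1]) genes else paste0(substr(sp, 1, 2), "_", genes)
    }
    for (sp in setdiff(unique(plat_species), d$species[1])) {
      non_pathway_core <- setdiff(core, pathway_genes)
      n_hom <- round(d$homology_fraction * length(non_pathway_core))
      mapped_genes <- c(pathway_genes, sample(non_pathway_core, n_hom))
      hm <- homology_map(setNames(species_id(sp, mapped_genes), mapped_genes),
                         source_species = d$species[1], target_species = sp)
      homology[[sp]] <- hm
      collections[[sp]] <- map_collection(col1, hm, min_size = d$pathway_size[1])
    }

    for (p in seq_len(d$n_platforms)) {
      sp <- plat_species[p]
      hm <- homology[[sp]]
      # platform measures: mappable core genes (in this species' id space)
      # plus platform-specific filler genes
      core_here <- if (sp == d$species[1]) core else unname(hm$pairs)
      n_fill <- max(0L, d$genes_per_platform - length(core_here))
      filler <- sprintf("%s_p%d_f%04d", substr(sp, 1, 2), p, seq_len(n_fill))
      genes <- c(core_here, filler)
      n_class_samples <- d$n_classes * d$n_samples_per_class
      n_total <- n_class_samples + d$n_background
      sample_class <- c(rep(classes, each = d$n_samples_per_class),
                        rep("background", d$n_background))
      sample_ids <- sprintf("P%d_%s_%02d", p, sample_class,
                            unlist(lapply(table(factor(sample_class, levels = unique(sample_class))),
                                          seq_len)))
      u <- matrix(runif(length(genes) * n_total), nrow = length(genes),
                  dimnames = list(genes, sample_ids))
      # apply class activations on the quantile scale
      for (ci in seq_len(d$n_classes)) {
        rows <- modulations[modulations$class == classes[ci], ]
        cols <- which(sample_class == classes[ci])
        for (r in seq_len(nrow(rows))) {
          members <- col1$sets[[rows$pathway[r]]]
          members_here <- species_id(sp, members)
          g <- which(genes %in% members_here)
          e <- rows$effect[r]
          if (rows$direction[r] > 0) {
            u[g, cols] <- 1 - (1 - u[g, cols]) * (1 - e)
          } else {
            u[g, cols] <- u[g, cols] * (1 - e)
          }
        }
      }
      offsets <- rnorm(length(genes), sd = 2)
      z <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
      f <- platform_transforms[[(p - 1) %% length(platform_transforms) + 1]]
      vals <- f(offsets + z)
      expression[[p]] <- expression_matrix(vals, platform = paste0("platform_", p),
                                           species = sp)
      truth_rows[[p]] <- tibble(sample = sample_ids,
                                platform = paste0("platform_", p),
                                species = sp, class = sample_class)
    }
    structure(list(expression = expression, collections = collections,
                   homology = homology, truth = bind_rows(truth_rows),
                   activations = activations, design = d),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d platforms, %d species, %d pathways, %d samples\n",
              length(x$expression), length(x$collections),
              x$design$n_pathways, nrow(x$truth)))
  invisible(x)
}

#' Fingerprint an entire synthetic corpus
#'
#' Builds per-platform backgrounds from the corpus's own background arrays
#' and fingerprints the class samples, returning one combined ternary matrix
#' over the pathway coordinates shared by all species.
#'
#' @param corpus A `synthetic_corpus`.
#' @param threshold Ternary threshold.
#' @param min_genes,n_min Passed to [pathway_scores()] /
#'   [build_background()].
#' @param collections Optional named list of replacement collections per
#'   species (e.g. from [random_genesets()]) to fingerprint against instead
#'   of the corpus's own.
#' @return A list: `prints` (ternary matrix, pathways x class samples),
#'   `poe` (POE matrix of the same shape), `labels` (class per sample), and
#'   `backgrounds` (per-platform `platform_background`s).
#' @export
fingerprint_corpus <- function(corpus, threshold = 0.001, min_genes = 3,
                               n_min = 50, collections = NULL) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  collections <- collections %||% corpus$collections
  common <- Reduce(intersect, lapply(collections, function(cc) names(cc$sets)))
  poe_cols <- list()
  fp_cols <- list()
  labels <- character()
  backgrounds <- list()
  for (p in seq_along(corpus$expression)) {
    em <- corpus$expression[[p]]
    col <- collections[[em$species]]
    truth_p <- corpus$truth[corpus$truth$platform == em$platform, ]
    bg_ids <- truth_p$sample[truth_p$class == "background"]
    cls_ids <- truth_p$sample[truth_p$class != "background"]
    scores <- pathway_scores(rank_transform(em), col, min_genes = min_genes)
    bg_scores <- scores
    bg_scores$scores <- scores$scores[, bg_ids, drop = FALSE]
    bg <- build_background(bg_scores, col, n_min = n_min)
    backgrounds[[em$platform]] <- bg
    cls_scores <- scores
    cls_scores$scores <- scores$scores[, cls_ids, drop = FALSE]
    poe <- poe_transform(cls_scores, bg)
    fp <- ternarize(poe, threshold = threshold)
    poe_cols[[p]] <- poe$poe[common, , drop = FALSE]
    fp_cols[[p]] <- fp$scores[common, , drop = FALSE]
    labels <- c(labels, truth_p$class[match(cls_ids, truth_p$sample)])
  }
  prints <- do.call(cbind, fp_cols)
  poe <- do.call(cbind, poe_cols)
  list(prints = prints, poe = poe, labels = labels, backgrounds = backgrounds)
}

#' Evolve a ternary fingerprint down a lineage tree
#'
#' Starting from a base fingerprint at the root, each edge mutates
#' `flips_per_edge` randomly chosen pathways by one ternary step up or down
#' (clamped to stay in -1..1); leaves are returned as the taxa of a
#' character matrix. With many characters and enough changes per edge the
#' generating topology is recoverable by parsimony.
#'
#' @param tree A rooted `ape::phylo` tree whose tip labels name the taxa.
#' @param base Integer ternary vector (named by pathway) for the root state.
#' @param flips_per_edge Number of pathway mutations per edge.
#' @param seed Integer seed.
#' @return A `character_matrix` (taxa x pathways).
#' @export
make_lineage <- function(tree, base, flips_per_edge, seed) {
  if (missing(seed) || is.null(seed)) abort("make_lineage requires an explicit seed")
  if (flips_per_edge < 0) abort("flips_per_edge must be >= 0")
  if (flips_per_edge > length(base)) abort("more flips than pathways")
  if (!all(base %in% c(-1L, 0L, 1L))) abort("base states must be in {-1, 0, 1}")
  ntip <- length(tree$tip.label)
  withr::with_seed(seed, {
    states <- matrix(NA_integer_, nrow = ntip + tree$Nnode, ncol = length(base))
    root <- ntip + 1L
    states[root, ] <- as.integer(base)
    edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
    # preorder: parents before children
    pre <- stats::reorder(tree, "cladewise")$edge
    for (e in seq_len(nrow(pre))) {
      parent <- pre[e, 1L]
      child <- pre[e, 2L]
      st <- states[parent, ]
      if (flips_per_edge > 0) {
        idx <- sample(length(st), flips_per_edge)
        step <- sample(c(-1L, 1L), flips_per_edge, replace = TRUE)
        st[idx] <- pmax(-1L, pmin(1L, st[idx] + step))
      }
      states[child, ] <- st
    }
    m <- states[seq_len(ntip), , drop = FALSE]
    rownames(m) <- tree$tip.label
    colnames(m) <- names(base) %||% sprintf("pathway_%03d", seq_along(base))
    character_matrix(m)
  })
}

#' Simulate survival times linked to a signature score
#'
#' Event times are exponential with hazard `lambda0 * exp(beta * score)`, so
#' `beta > 0` makes high-scoring samples die faster. Censoring is applied
#' independently: each sample is censored with probability `censor_rate`, at
#' a time uniform on `(0, t_event)`, which achieves the requested expected
#' censoring fraction exactly.
#'
#' @param scores Named numeric vector of per-sample signature scores.
#' @param beta Log-hazard increase per score unit.
#' @param censor_rate Probability of censoring, in `[0, 1)`.
#' @param lambda0 Baseline hazard (default 0.1).
#' @param seed Integer seed.
#' @return A `survival_table` aligned with `scores`.
#' @export
make_survival <- function(scores, beta, censor_rate = 0.3, lambda0 = 0.1, seed) {
  if (missing(seed) || is.null(seed)) abort("make_survival requires an explicit seed")
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate must be in [0, 1)")
  withr::with_seed(seed, {
    n <- length(scores)
    t_event <- rexp(n, rate = lambda0 * exp(beta * scores))
    censored <- runif(n) < censor_rate
    time <- ifelse(censored, runif(n) * t_event, t_event)
    survival_table(names(scores) %||% paste0("S", seq_len(n)),
                   time, as.integer(!censored))
  })
}
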
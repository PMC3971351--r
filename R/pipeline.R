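#' Run a pipeline stage from a config
#'
#' Thin orchestration layer over the package functions: each command reads
#' its inputs from the paths in `config`, runs one stage, and writes its
#' outputs atomically (tempfile + rename) with a provenance header (tool
#' version, config hash, seed). Inputs are never mutated; re-running a
#' command with identical config and inputs reproduces its outputs byte for
#' byte. Any stage failure aborts with the stage named.
#'
#' Config keys by command (all paths; parameters have the published
#' defaults):
#' \describe{
#'   \item{simulate}{`out_dir`, `seed`, optional `design` overrides for
#'     [corpus_design()]. Writes per-platform expression TSVs, a GMT per
#'     species, homology TSVs and a truth table.}
#'   \item{background}{`expression`, `gmt`, `platform`, `species`,
#'     `background_out`; optional `min_genes`, `n_min`.}
#'   \item{fingerprint}{`expression`, `gmt`, `background`, `platform`,
#'     `species`, `fingerprint_out`; optional `poe_out`, `threshold`
#'     (default 0.001), `min_genes`.}
#'   \item{consensus}{`fingerprints`, `consensus_out`, `t`.}
#'   \item{retrieve}{`consensus`, `corpus`, `retrieve_out`.}
#'   \item{benchmark}{`poe`, `labels` (2-column TSV sample/label),
#'     `benchmark_out`; optional `thresholds` (default 0.001).}
#'   \item{phylo}{`fingerprints`, `groups` (2-column TSV sample/group),
#'     `tree_out`; optional `consensus_t` (default 0.75), `bootstrap`
#'     (default 100), `seed`.}
#'   \item{sras}{`fingerprints`, `groups`, `signature_out`; or
#'     `fingerprints`, `signature`, `survival`, `survival_out` with optional
#'     `permutations` (default 1000) and `seed`.}
#' }
#'
#' @param config Named list, or path to a YAML file of the same shape.
#' @param command One of `simulate`, `background`, `fingerprint`,
#'   `consensus`, `retrieve`, `benchmark`, `phylo`, `sras`.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "background", "fingerprint",
                                     "consensus", "retrieve", "benchmark",
                                     "phylo", "sras")) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stage <- function(expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", command, conditionMessage(e)))
    })
  }
  written <- stage(switch(command,
    simulate = cmd_simulate(config),
    background = cmd_background(config),
    fingerprint = cmd_fingerprint(config),
    consensus = cmd_consensus(config),
    retrieve = cmd_retrieve(config),
    benchmark = cmd_benchmark(config),
    phylo = cmd_phylo(config),
    sras = cmd_sras(config)
  ))
  invisible(written)
}

provenance <- function(config) {
  c(sprintf("fingerprintr %s", the_tool_version()),
    sprintf("config_hash %s", hash(config)),
    if (!is.null(config$seed)) sprintf("seed %s", config$seed))
}

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  path
}

write_tibble_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

need <- function(config, keys) {
  miss <- keys[!keys %in% names(config)]
  if (length(miss)) abort(paste0("config missing: ", paste(miss, collapse = ", ")))
}

need_file <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(sprintf("input '%s' not found; run the '%s' command first",
                  path, produced_by))
  }
}

read_two_col <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

cmd_simulate <- function(config) {
  need(config, c("out_dir", "seed"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- config$design %||% list()
  args$seed <- config$seed
  design <- do.call(corpus_design, args)
  corpus <- make_corpus(design)
  hdr <- provenance(config)
  out <- character()
  for (em in corpus$expression) {
    p <- file.path(config$out_dir, paste0("expression_", em$platform, ".tsv"))
    atomic_write(p, function(t) write_matrix_tsv(em$values, t, "gene_id", hdr))
    out <- c(out, p)
  }
  for (sp in names(corpus$collections)) {
    p <- file.path(config$out_dir, paste0("genesets_", sp, ".gmt"))
    atomic_write(p, function(t) write_gmt(corpus$collections[[sp]], t))
    out <- c(out, p)
  }
  for (sp in names(corpus$homology)) {
    p <- file.path(config$out_dir, paste0("homology_", sp, ".tsv"))
    hm <- corpus$homology[[sp]]
    atomic_write(p, function(t) {
      utils::write.table(data.frame(names(hm$pairs), unname(hm$pairs)), t,
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    })
    out <- c(out, p)
  }
  p <- file.path(config$out_dir, "truth.tsv")
  atomic_write(p, function(t) write_tibble_tsv(corpus$truth, t, hdr))
  c(out, p)
}

pipeline_scores <- function(config) {
  em <- read_expression(config$expression, platform = config$platform,
                        species = config$species)
  col <- read_gmt(config$gmt, species = config$species)
  list(scores = pathway_scores(rank_transform(em), col,
                               min_genes = config$min_genes %||% 3),
       col = col)
}

cmd_background <- function(config) {
  need(config, c("expression", "gmt", "platform", "species", "background_out"))
  need_file(config$expression, "simulate")
  ps <- pipeline_scores(config)
  bg <- build_background(ps$scores, ps$col, n_min = config$n_min %||% 50)
  atomic_write(config$background_out, function(t) write_background(bg, t))
  config$background_out
}

cmd_fingerprint <- function(config) {
  need(config, c("expression", "gmt", "background", "platform", "species",
                 "fingerprint_out"))
  need_file(config$background, "background")
  ps <- pipeline_scores(config)
  bg <- read_background(config$background)
  poe <- poe_transform(ps$scores, bg)
  fp <- ternarize(poe, threshold = config$threshold %||% 0.001)
  hdr <- provenance(config)
  out <- atomic_write(config$fingerprint_out, function(t) {
    write_matrix_tsv(fp$scores, t, "pathway", hdr)
  })
  if (!is.null(config$poe_out)) {
    atomic_write(config$poe_out, function(t) {
      write_matrix_tsv(poe$poe, t, "pathway", hdr)
    })
    out <- c(out, config$poe_out)
  }
  out
}

cmd_consensus <- function(config) {
  need(config, c("fingerprints", "consensus_out", "t"))
  need_file(config$fingerprints, "fingerprint")
  fp <- read_fingerprints(config$fingerprints)
  cons <- consensus_fingerprint(fp, t = config$t)
  df <- tibble(pathway = names(cons$scores), score = unname(cons$scores))
  atomic_write(config$consensus_out, function(t) {
    write_tibble_tsv(df, t, provenance(config))
  })
  config$consensus_out
}

cmd_retrieve <- function(config) {
  need(config, c("consensus", "corpus", "retrieve_out"))
  need_file(config$consensus, "consensus")
  need_file(config$corpus, "fingerprint")
  ctab <- utils::read.delim(config$consensus, comment.char = "#")
  cons <- structure(list(scores = setNames(as.integer(ctab$score), ctab$pathway),
                         t = NA_real_, n_samples = NA_integer_),
                    class = "consensus_fingerprint")
  corpus <- read_fingerprints(config$corpus)
  ranked <- rank_corpus(cons, corpus)
  atomic_write(config$retrieve_out, function(t) {
    write_tibble_tsv(ranked, t, provenance(config))
  })
  config$retrieve_out
}

cmd_benchmark <- function(config) {
  need(config, c("poe", "labels", "benchmark_out"))
  need_file(config$poe, "fingerprint")
  poe <- read_matrix_tsv(config$poe)
  labels <- read_two_col(config$labels)
  labels <- labels[colnames(poe)]
  sweep <- threshold_sweep(poe, labels,
                           thresholds = unlist(config$thresholds %||% 0.001),
                           seed = config$seed %||% 1)
  atomic_write(config$benchmark_out, function(t) {
    write_tibble_tsv(sweep, t, provenance(config))
  })
  config$benchmark_out
}

cmd_phylo <- function(config) {
  need(config, c("fingerprints", "groups", "tree_out"))
  need_file(config$fingerprints, "fingerprint")
  fp <- read_fingerprints(config$fingerprints)
  groups <- read_two_col(config$groups)
  groups <- groups[colnames(fp$scores)]
  t_cons <- config$consensus_t %||% 0.75
  taxa <- sort(unique(groups))
  chars <- t(vapply(taxa, function(g) {
    consensus_fingerprint(fp$scores[, groups == g, drop = FALSE], t = t_cons)$scores
  }, integer(nrow(fp$scores))))
  rownames(chars) <- taxa
  res <- bootstrap_support(character_matrix(chars),
                           n_reps = config$bootstrap %||% 100,
                           seed = config$seed %||% 1)
  atomic_write(config$tree_out, function(t) write_lineage_tree(res, t))
  config$tree_out
}

cmd_sras <- function(config) {
  need(config, "fingerprints")
  need_file(config$fingerprints, "fingerprint")
  fp <- read_fingerprints(config$fingerprints)
  out <- character()
  if (!is.null(config$signature_out)) {
    need(config, "groups")
    groups <- read_two_col(config$groups)
    sig <- differential_signature(fp, groups[colnames(fp$scores)],
                                  t_cons = config$consensus_t %||% 0.75)
    atomic_write(config$signature_out, function(t) {
      write_tibble_tsv(as_tibble(sig), t, provenance(config))
    })
    out <- c(out, config$signature_out)
  }
  if (!is.null(config$survival_out)) {
    need(config, c("signature", "survival"))
    stab <- utils::read.delim(config$signature, comment.char = "#")
    sig <- pathway_signature(stab$pathway, stab$sign)
    surv <- read_survival_table(config$survival)
    surv <- surv[match(colnames(fp$scores), surv$sample_id), ]
    bgd <- permutation_background(fp, surv, sig,
                                  n_perm = config$permutations %||% 1000,
                                  seed = config$seed %||% 1)
    df <- tibble(quantity = c("observed_p", "background_percentile",
                              "n_permutations_used", "n_skipped"),
                 value = c(bgd$observed_p, bgd$percentile,
                           length(bgd$p_values), bgd$n_skipped))
    atomic_write(config$survival_out, function(t) {
      write_tibble_tsv(df, t, provenance(config))
    })
    out <- c(out, config$survival_out)
  }
  if (length(out) == 0L) abort("sras config names neither signature_out nor survival_out")
  out
}
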
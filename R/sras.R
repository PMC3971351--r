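#' Pathway signatures
#'
#' An ordered set of pathways with an expected direction of activity
#' (+1 overexpressed, -1 underexpressed), e.g. a stemness signature shared
#' by leukemic and normal stem cells.
#'
#' @param pathways Character vector of pathway names.
#' @param signs Integer vector in {-1, +1}, one per pathway.
#' @return An object of class `pathway_signature` (a tibble with columns
#'   `pathway` and `sign`).
#' @export
pathway_signature <- function(pathways, signs) {
  if (length(pathways) != length(signs)) abort("one sign per pathway required")
  if (length(signs) > 0 && !all(signs %in% c(-1L, 1L))) abort("signs must be -1 or +1")
  if (anyDuplicated(pathways)) abort("duplicate pathway in signature")
  structure(tibble(pathway = as.character(pathways), sign = as.integer(signs)),
            class = c("pathway_signature", class(tibble())))
}

#' Stem-versus-progenitor differential signature
#'
#' A pathway enters the signature when both stem-cell groups (leukemic and
#' normal) agree on a non-zero consensus call and the progenitor group's
#' consensus differs from that call. The shared stem-cell call provides the
#' signature sign. The rule is symmetric in the two stem groups.
#'
#' @param prints A `fingerprint_matrix` (or ternary matrix) over all samples.
#' @param group Per-sample labels from
#'   `{"leukemic_stem", "normal_stem", "progenitor"}` (all three non-empty).
#' @param t_cons Consensus threshold used for the three group consensus
#'   fingerprints (default 0.75).
#' @return A `pathway_signature`; empty with a warning when no pathway
#'   satisfies the rule.
#' @export
differential_signature <- function(prints, group, t_cons = 0.75) {
  m <- as_score_matrix(prints)
  group <- as.character(group)
  if (length(group) != ncol(m)) abort("one group label per sample required")
  needed <- c("leukemic_stem", "normal_stem", "progenitor")
  missing_g <- setdiff(needed, unique(group))
  if (length(missing_g) > 0L) {
    abort(paste0("empty group(s): ", paste(missing_g, collapse = ", ")))
  }
  cons <- lapply(needed, function(g) {
    consensus_fingerprint(m[, group == g, drop = FALSE], t = t_cons)$scores
  })
  names(cons) <- needed
  s <- cons$leukemic_stem
  keep <- s != 0L & cons$normal_stem == s & cons$progenitor != s
  if (!any(keep)) {
    warn("no pathway satisfies the stem-versus-progenitor rule; empty signature")
    return(pathway_signature(character(), integer()))
  }
  pathway_signature(rownames(m)[keep], s[keep])
}

#' Intersect two signatures
#'
#' Keeps the pathways present in both signatures with equal signs; order
#' follows the first argument. Used to form cross-species signatures from
#' per-species ones.
#'
#' @param a,b `pathway_signature` objects.
#' @return A `pathway_signature`.
#' @export
intersect_signatures <- function(a, b) {
  hit <- match(a$pathway, b$pathway)
  keep <- !is.na(hit) & a$sign == b$sign[hit]
  pathway_signature(a$pathway[keep], a$sign[keep])
}

#' Signature score of a sample
#'
#' The plain sum of the sample's ternary pathway scores across the signature
#' pathways (range `[-k, +k]` for a k-pathway signature). A sign-weighted
#' variant, `sum(sign_i * F_i)`, is available via `weighted = TRUE`.
#'
#' @param prints A single fingerprint vector, or a `fingerprint_matrix` /
#'   ternary matrix for many samples at once.
#' @param sig A non-empty `pathway_signature` whose pathways all exist among
#'   the fingerprint coordinates.
#' @param weighted Use the sign-weighted sum (default `FALSE`, the plain sum).
#' @return Named integer vector of per-sample scores.
#' @export
sras_score <- function(prints, sig, weighted = FALSE) {
  if (nrow(sig) == 0L) abort("empty signature")
  m <- if (inherits(prints, "fingerprint_matrix")) prints$scores
       else if (is.matrix(prints)) prints
       else matrix(prints, ncol = 1, dimnames = list(names(prints), "S1"))
  missing_p <- setdiff(sig$pathway, rownames(m))
  if (length(missing_p) > 0L) {
    abort(paste0("signature pathway(s) absent from the fingerprint: ",
                 paste(missing_p, collapse = ", ")))
  }
  sub <- m[sig$pathway, , drop = FALSE]
  w <- if (weighted) sig$sign else rep(1L, nrow(sig))
  out <- as.integer(colSums(sub * w))
  names(out) <- colnames(m)
  out
}

#' Exact two-group stratification of 1-D scores
#'
#' Splits a score vector into "low" and "high" groups by exact
#' one-dimensional 2-means: every threshold between adjacent distinct sorted
#' values is evaluated and the split minimizing the within-group sum of
#' squares is chosen (ties broken toward the smaller low group). This is
#' the global 2-means optimum — solving it by scan removes any dependence
#' on random initialization.
#'
#' @param scores Numeric vector with >= 2 distinct values.
#' @return Factor of `"low"`/`"high"` per sample; the "high" group always
#'   has the larger mean. The chosen cut value is attached as attribute
#'   `"cut"` (samples with `score <= cut` are "low").
#' @export
stratify_two_groups <- function(scores) {
  ux <- sort(unique(scores))
  if (length(ux) < 2L) abort("all scores identical: cannot stratify")
  s <- sort(scores)
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  best_wss <- Inf
  best_cut <- NA_real_
  for (i in seq_len(n - 1L)) {
    if (s[i] == s[i + 1L]) next
    wss <- (cs2[i] - cs[i]^2 / i) +
      ((cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i))
    if (wss < best_wss - 1e-12) {
      best_wss <- wss
      best_cut <- s[i]
    }
  }
  grp <- factor(ifelse(scores <= best_cut, "low", "high"),
                levels = c("low", "high"))
  attr(grp, "cut") <- best_cut
  grp
}

#' Survival tables
#'
#' @param sample_id Sample identifiers.
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A `survival_table` tibble.
#' @export
survival_table <- function(sample_id, time, event) {
  if (any(time < 0)) abort("follow-up times must be >= 0")
  if (!all(event %in% c(0, 1))) abort("event indicators must be 0 or 1")
  structure(tibble(sample_id = as.character(sample_id), time = as.numeric(time),
                   event = as.integer(event)),
            class = c("survival_table", class(tibble())))
}

#' Read a survival table from 3-column TSV
#' @param path TSV with header columns `sample_id`, `time`, `event`.
#' @return A `survival_table`.
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  survival_table(tab$sample_id, tab$time, tab$event)
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Standard log-rank test: at each distinct event time the observed events
#' in one group are compared with their hypergeometric expectation given the
#' numbers at risk, and the accumulated `(O - E)^2 / V` is referred to a
#' chi-square with 1 df. Kaplan-Meier curves per group are returned for
#' plotting; the statistic and p-value are the contractual output.
#'
#' @param groups Two-level factor (or vector) of group assignments, aligned
#'   with `surv` rows.
#' @param surv A `survival_table`.
#' @return A `logrank_result`: list with `statistic`, `p_value`, `n` per
#'   group, `fit` (the `survfit` object) and `curves` (tidy tibble of the
#'   step curves).
#' @export
logrank_test <- function(groups, surv) {
  groups <- factor(groups)
  if (length(groups) != nrow(surv)) abort("one group per survival record required")
  if (nlevels(droplevels(groups)) != 2L) abort("exactly two non-empty groups required")
  if (sum(surv$event) == 0L) abort("no events observed")
  df <- data.frame(time = surv$time, event = surv$event, group = groups)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- sd_fit$chisq
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(km$strata), km$strata)
  curves <- tibble(group = sub("^group=", "", strata), time = km$time,
                   surv = km$surv, n_risk = km$n.risk, n_event = km$n.event)
  structure(list(statistic = unname(stat), p_value = unname(p),
                 n = table(groups), fit = km, curves = curves),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.3f, p = %.4g (n = %s)\n",
              x$statistic, x$p_value,
              paste(sprintf("%s:%d", names(x$n), x$n), collapse = ", ")))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_result`.
#' @param ... Unused.
#' @export
glance.logrank_result <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, df = 1L,
         n = sum(x$n), n_events = sum(x$fit$n.event))
}

#' Kaplan-Meier plot of a log-rank result
#' @param object A `logrank_result`.
#' @param ... Unused.
#' @return A ggplot of the step survival curves.
#' @export
autoplot.logrank_result <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability")
}

#' Permutation background for signature survival stratification
#'
#' Repeats the score-stratify-test chain with random signatures of the same
#' size (pathways drawn uniformly without replacement from the fingerprint),
#' producing a background distribution of log-rank p-values against which
#' the observed signature's p-value is ranked. Permutations where the
#' stratification or the test is degenerate (constant scores, empty group,
#' no events) are skipped and counted.
#'
#' @param prints A `fingerprint_matrix` (or ternary matrix) over the cohort.
#' @param surv A `survival_table` aligned with the fingerprint columns.
#' @param sig An observed `pathway_signature`, or an integer signature size
#'   (in which case only the background is computed).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param weighted Passed to [sras_score()].
#' @return A `permutation_background`: list with `observed_p` (or `NA`),
#'   `percentile` (fraction of background p-values <= observed), `p_values`
#'   (background vector), `n_skipped`, `sig_size`, `n_perm`.
#' @export
permutation_background <- function(prints, surv, sig, n_perm = 1000, seed = 1,
                                   weighted = FALSE) {
  m <- as_score_matrix(prints)
  if (nrow(surv) != ncol(m)) abort("survival table not aligned with fingerprints")
  run_one <- function(signature) {
    scores <- sras_score(m, signature, weighted = weighted)
    if (length(unique(scores)) < 2L) return(NA_real_)
    grp <- stratify_two_groups(scores)
    if (any(table(grp) == 0L)) return(NA_real_)
    tryCatch(logrank_test(grp, surv)$p_value, error = function(e) NA_real_)
  }
  observed_p <- NA_real_
  if (inherits(sig, "pathway_signature")) {
    sig_size <- nrow(sig)
    observed_p <- run_one(sig)
  } else {
    sig_size <- as.integer(sig)
  }
  if (sig_size > nrow(m)) abort("signature size exceeds the number of pathways")
  p_values <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pw <- sample(rownames(m), sig_size)
    run_one(pathway_signature(pw, rep(1L, sig_size)))
  }, 0))
  n_skipped <- sum(is.na(p_values))
  p_values <- p_values[!is.na(p_values)]
  percentile <- if (is.na(observed_p) || length(p_values) == 0L) NA_real_
                else mean(p_values <= observed_p)
  structure(list(observed_p = observed_p, percentile = percentile,
                 p_values = p_values, n_skipped = n_skipped,
                 sig_size = sig_size, n_perm = n_perm),
            class = "permutation_background")
}

#' @export
print.permutation_background <- function(x, ...) {
  cat(sprintf("<permutation_background> size-%d signature, %d/%d usable permutations",
              x$sig_size, length(x$p_values), x$n_perm))
  if (!is.na(x$observed_p)) {
    cat(sprintf("; observed p = %.4g (percentile %.3f)", x$observed_p, x$percentile))
  }
  cat("\n")
  invisible(x)
}
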
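#' Fit a two-component uniform-normal mixture by EM
#'
#' Models a vector of pathway expression scores as
#' `y ~ pi * U(lo, hi) + (1 - pi) * N(mu, sigma^2)`. The normal component is
#' the core of typical scores for the pathway on this platform; the uniform
#' component absorbs outlying scores, i.e. significantly high or low pathway
#' expression. The uniform support is held fixed at the observed range padded
#' by `eps_frac` of the range on each side — estimating a free uniform
#' support by maximum likelihood is ill-posed, and a fixed support matches
#' the outlier semantics. With the support fixed, EM over `(pi, mu, sigma)`
#' is a standard two-component mixture fit and the log-likelihood is
#' non-decreasing at every iteration.
#'
#' The fit is deterministic: initialization is `pi = 0.1`, `mu = median(y)`,
#' `sigma = 1.4826 * mad(y)` (falling back to `sd(y)` if the MAD is zero).
#'
#' @param values Numeric vector of pathway expression scores from background
#'   arrays of one platform.
#' @param n_min Minimum observations required (default 50).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param eps_frac Padding of the uniform support as a fraction of the
#'   observed range (default 0.001).
#' @param pi0 Initial outlier-component weight (default 0.1).
#' @param sigma_floor_frac Lower bound on `sigma` as a fraction of the
#'   support width (default 1e-6).
#' @return An object of class `mixture_fit` with fields `pi_uniform`, `mu`,
#'   `sigma`, `lo`, `hi`, `loglik`, `loglik_trace`, `n_obs`, `converged`,
#'   `iterations`.
#' @export
fit_uniform_normal_em <- function(values, n_min = 50, tol = 1e-8,
                                  max_iter = 1000, eps_frac = 0.001,
                                  pi0 = 0.1, sigma_floor_frac = 1e-6) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < n_min) abort(sprintf("need >= %d observations, got %d", n_min, n))
  rng <- range(values)
  if (rng[1] == rng[2]) abort("constant input: mixture is unidentifiable")
  eps <- eps_frac * (rng[2] - rng[1])
  lo <- rng[1] - eps
  hi <- rng[2] + eps
  dunif_c <- 1 / (hi - lo)
  sigma_floor <- sigma_floor_frac * (hi - lo)

  pi_u <- pi0
  mu <- median(values)
  sigma <- 1.4826 * mad(values, constant = 1)
  if (sigma <= 0) sigma <- sd(values)
  sigma <- max(sigma, sigma_floor)

  loglik_of <- function(pi_u, mu, sigma) {
    sum(log(pi_u * dunif_c + (1 - pi_u) * dnorm(values, mu, sigma)))
  }
  ll <- loglik_of(pi_u, mu, sigma)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: posterior membership in the uniform (outlier) component
    fu <- pi_u * dunif_c
    fn <- (1 - pi_u) * dnorm(values, mu, sigma)
    w <- fu / (fu + fn)
    # M-step
    pi_u <- mean(w)
    wn <- 1 - w
    sw <- sum(wn)
    if (sw > 0) {
      mu <- sum(wn * values) / sw
      sigma <- sqrt(sum(wn * (values - mu)^2) / sw)
    }
    sigma <- max(sigma, sigma_floor)
    ll_new <- loglik_of(pi_u, mu, sigma)
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  structure(
    list(pi_uniform = pi_u, mu = mu, sigma = sigma, lo = lo, hi = hi,
         loglik = ll, loglik_trace = trace, n_obs = n,
         converged = converged, iterations = iter),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> pi_uniform=%.4f mu=%.4g sigma=%.4g (n=%d, %s after %d iter)\n",
              x$pi_uniform, x$mu, x$sigma, x$n_obs,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' @rdname fit_uniform_normal_em
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(term = c("pi_uniform", "mu", "sigma", "lo", "hi"),
         estimate = c(x$pi_uniform, x$mu, x$sigma, x$lo, x$hi))
}

#' @rdname fit_uniform_normal_em
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(logLik = x$loglik, iterations = x$iterations,
         converged = x$converged, n_obs = x$n_obs)
}

#' Densities of a fitted mixture for plotting
#' @param object A `mixture_fit`.
#' @param n Grid size.
#' @param ... Unused.
#' @return A ggplot of the component and total densities over the support.
#' @export
autoplot.mixture_fit <- function(object, n = 512, ...) {
  y <- seq(object$lo, object$hi, length.out = n)
  du <- object$pi_uniform / (object$hi - object$lo)
  dn <- (1 - object$pi_uniform) * dnorm(y, object$mu, object$sigma)
  df <- tibble(
    score = rep(y, 3),
    density = c(rep(du, n), dn, du + dn),
    component = rep(c("uniform (outlier)", "normal (core)", "mixture"), each = n)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$density,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pathway expression score", y = "density")
}

#' Build a platform background
#'
#' Fits one uniform-normal mixture per pathway from the score matrix of a
#' collection of background arrays that all share one platform. The
#' background is the static null against which any later sample on that
#' platform is normalized; it stores the collection hash so POE cannot be
#' computed against a different (or reordered) collection.
#'
#' Pathways that cannot be fitted are recorded as absent with a reason:
#' `"unscored"` (no scores in the matrix), `"insufficient_data"` (< `n_min`
#' observations) or `"constant"`.
#'
#' @param score_matrix A `pathway_score_matrix` over the background samples.
#' @param col The `geneset_collection` the scores were computed against.
#' @param n_min,tol,max_iter,eps_frac Passed to [fit_uniform_normal_em()].
#' @return An object of class `platform_background`.
#' @export
build_background <- function(score_matrix, col, n_min = 50, tol = 1e-8,
                             max_iter = 1000, eps_frac = 0.001) {
  stopifnot(inherits(score_matrix, "pathway_score_matrix"),
            inherits(col, "geneset_collection"))
  if (!identical(score_matrix$collection_id, collection_hash(col))) {
    abort("score matrix was computed against a different collection")
  }
  fits <- vector("list", length(col))
  names(fits) <- names(col$sets)
  for (p in names(col$sets)) {
    y <- score_matrix$scores[p, ]
    y <- y[!is.na(y)]
    if (length(y) == 0L) {
      fits[[p]] <- list(reason = "unscored")
    } else if (length(y) < n_min) {
      fits[[p]] <- list(reason = "insufficient_data")
    } else if (min(y) == max(y)) {
      fits[[p]] <- list(reason = "constant")
    } else {
      fits[[p]] <- fit_uniform_normal_em(y, n_min = n_min, tol = tol,
                                         max_iter = max_iter,
                                         eps_frac = eps_frac)
    }
  }
  structure(
    list(platform = score_matrix$platform,
         collection_id = score_matrix$collection_id,
         fits = fits, n_background = ncol(score_matrix$scores),
         tool_version = the_tool_version()),
    class = "platform_background"
  )
}

#' @export
print.platform_background <- function(x, ...) {
  ok <- sum(vapply(x$fits, inherits, NA, "mixture_fit"))
  cat(sprintf("<platform_background> platform '%s': %d/%d pathways fitted (n=%d arrays)\n",
              x$platform, ok, length(x$fits), x$n_background))
  invisible(x)
}

#' Serialize / restore a platform background
#'
#' Backgrounds are immutable, versioned JSON files; numeric fields are
#' written at full precision so a save/load round trip reproduces every fit
#' bit-identically.
#'
#' @param bg A `platform_background`.
#' @param path Output path.
#' @return `path` (writer) or a `platform_background` (reader).
#' @export
write_background <- function(bg, path) {
  ser <- unclass(bg)
  ser$fits <- lapply(bg$fits, function(f) {
    if (inherits(f, "mixture_fit")) c(unclass(f), list(.kind = "fit")) else f
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  raw$fits <- lapply(raw$fits, function(f) {
    if (identical(f$.kind, "fit")) {
      f$.kind <- NULL
      structure(f, class = "mixture_fit")
    } else f
  })
  structure(raw[c("platform", "collection_id", "fits", "n_background",
                  "tool_version")],
            class = "platform_background")
}

#' Signed probability of expression (POE)
#'
#' Converts pathway expression scores into signed probabilities of belonging
#' to the outlier component of the platform background. For a score `y` with
#' fit `(pi, mu, sigma, lo, hi)` the posterior outlier probability is
#' `p = pi * f_U(y) / (pi * f_U(y) + (1 - pi) * f_N(y))`, and
#' `POE = p * sign(y - mu)`, so values near +1 indicate significantly high
#' pathway expression relative to the platform, values near -1 significantly
#' low, and values near 0 unremarkable expression. POE lies in (-1, 1).
#'
#' @param scores A `pathway_score_matrix`.
#' @param bg A `platform_background` with matching platform and collection id.
#' @return A `poe_matrix`: pathways-by-samples values in (-1, 1), `NA` where
#'   the score or fit is absent.
#' @export
poe_transform <- function(scores, bg) {
  stopifnot(inherits(scores, "pathway_score_matrix"),
            inherits(bg, "platform_background"))
  if (!identical(scores$collection_id, bg$collection_id)) {
    abort("background was built for a different gene-set collection")
  }
  if (!identical(scores$platform, bg$platform)) {
    abort(sprintf("background platform '%s' does not match score platform '%s'",
                  bg$platform, scores$platform))
  }
  poe <- matrix(NA_real_, nrow = nrow(scores$scores), ncol = ncol(scores$scores),
                dimnames = dimnames(scores$scores))
  for (p in rownames(poe)) {
    f <- bg$fits[[p]]
    if (!inherits(f, "mixture_fit")) next
    y <- scores$scores[p, ]
    fu <- f$pi_uniform / (f$hi - f$lo)
    fn <- (1 - f$pi_uniform) * dnorm(y, f$mu, f$sigma)
    prob <- fu / (fu + fn)
    prob[fu == 0] <- 0
    poe[p, ] <- prob * sign(y - f$mu)
  }
  structure(list(poe = poe, platform = scores$platform,
                 species = scores$species,
                 collection_id = scores$collection_id),
            class = "poe_matrix")
}

#' @export
print.poe_matrix <- function(x, ...) {
  cat(sprintf("<poe_matrix> %d pathways x %d samples, platform '%s'\n",
              nrow(x$poe), ncol(x$poe), x$platform))
  invisible(x)
}
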
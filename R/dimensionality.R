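# Participation-ratio effective dimensionality with equal-n subsampling
# and the three-way condition comparison.

#' Participation ratio of an eigenvalue spectrum
#'
#' `PR = 1 / sum(lbar_i^2)` with `lbar_i = lambda_i / sum(lambda)`. Equals
#' N for N equal nonzero eigenvalues and 1 for a rank-1 spectrum.
#'
#' @param lambda non-negative eigenvalues.
#' @return effective dimensionality (>= 1).
#' @examples
#' pr_from_eigenvalues(c(3, 1))  # 1.6
#' @export
pr_from_eigenvalues <- function(lambda) {
  lambda <- as.numeric(lambda)
  stopifnot(all(is.finite(lambda)), all(lambda >= 0))
  if (sum(lambda) == 0) stop("degenerate input: all eigenvalues are zero")
  lbar <- lambda / sum(lambda)
  1 / sum(lbar^2)
}

#' Participation-ratio effective dimensionality of a set of maps
#'
#' Eigenvalues are taken from the feature-centered sample covariance of
#' the maps (the same spectrum the PCA decomposes, so PR and PCA agree);
#' eigenvalues below `1e-12 * lambda_max` are treated as zero.
#'
#' @param maps n x parcels matrix, `n >= 3`.
#' @return participation ratio, a real in `[1, n - 1]`.
#' @export
participation_ratio <- function(maps) {
  maps <- as.matrix(maps)
  stopifnot(nrow(maps) >= 3L)
  x <- scale(maps, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-13)) stop("degenerate input: zero-variance data")
  ev <- eigen(tcrossprod(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0) / (nrow(maps) - 1)
  ev[ev < 1e-12 * max(ev)] <- 0
  pr_from_eigenvalues(ev)
}

#' Distribution of participation ratios over equal-n subsamples
#'
#' Sample size affects the participation ratio, so conditions are compared
#' at a common subset size `n_sub`. Three schemes: `all_combinations`
#' enumerates every size-`n_sub` subset; `jackknife` is the leave-one-out
#' special case (requires `n - n_sub = 1`); `random_k` draws `n_draws`
#' distinct subsets uniformly.
#'
#' @param maps n x parcels matrix.
#' @param n_sub common subset size (default 22).
#' @param scheme subsampling scheme.
#' @param n_draws subsets drawn under `random_k`.
#' @param seed integer seed (`random_k` only).
#' @param condition optional condition label carried on the result.
#' @return a `pr_distribution`: `condition`, `pr_values`, `scheme`,
#'   `n_sub`.
#' @export
pr_distribution <- function(maps, n_sub = 22L,
                            scheme = c("all_combinations", "jackknife",
                                       "random_k"),
                            n_draws = 100L, seed = 1L, condition = NULL) {
  scheme <- match.arg(scheme)
  maps <- as.matrix(maps)
  n <- nrow(maps)
  stopifnot(is_count(n_sub), n_sub >= 3L, n >= n_sub)
  subsets <- switch(
    scheme,
    all_combinations = {
      n_comb <- choose(n, n_sub)
      if (n_comb > 1e5)
        stop(sprintf("C(%d, %d) = %.3g subsets; use scheme = 'random_k'",
                     n, n_sub, n_comb))
      utils::combn(n, n_sub, simplify = FALSE)
    },
    jackknife = {
      if (n - n_sub != 1L)
        stop("jackknife requires n - n_sub = 1 (leave-one-out)")
      lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
    },
    random_k = {
      stopifnot(is_count(n_draws))
      if (n_draws > choose(n, n_sub))
        stop("n_draws exceeds the number of distinct subsets")
      with_seed(seed, {
        seen <- character(0)
        out <- vector("list", n_draws)
        got <- 0L
        while (got < n_draws) {
          cand <- sort(sample(n, n_sub))
          key <- paste(cand, collapse = ",")
          if (!(key %in% seen)) {
            got <- got + 1L
            out[[got]] <- cand
            seen <- c(seen, key)
          }
        }
        out
      })
    }
  )
  pr_values <- vapply(subsets, function(idx)
    participation_ratio(maps[idx, , drop = FALSE]), numeric(1))
  structure(
    list(condition = condition %||% NA_character_, pr_values = pr_values,
         scheme = scheme, n_sub = as.integer(n_sub)),
    class = "pr_distribution"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pr_distribution <- function(x, ...) {
  cat(sprintf("pr_distribution (%s, %s, n_sub = %d): %d values, %.2f +/- %.2f\n",
              x$condition, x$scheme, x$n_sub, length(x$pr_values),
              mean(x$pr_values), stats::sd(x$pr_values)))
  invisible(x)
}

#' Compare effective-dimensionality distributions across conditions
#'
#' One-way ANOVA over the pooled PR values (df = groups - 1, total - groups)
#' followed by all pairwise Welch t-tests with Bonferroni-multiplied
#' p-values.
#'
#' @param dists list of `pr_distribution` objects (>= 2), each with >= 3
#'   values.
#' @return list: `anova` (data frame F, df1, df2, p), `posthoc` (data
#'   frame per pair: t, df, p, p_bonferroni), `group_stats`.
#' @export
compare_conditions <- function(dists) {
  stopifnot(length(dists) >= 2L,
            all(vapply(dists, inherits, logical(1), "pr_distribution")),
            all(vapply(dists, function(d) length(d$pr_values), integer(1)) >= 3L))
  labels <- vapply(seq_along(dists), function(i)
    if (is.na(dists[[i]]$condition)) paste0("cond", i) else
      dists[[i]]$condition, character(1))
  values <- unlist(lapply(dists, `[[`, "pr_values"))
  group <- factor(rep(labels, vapply(dists, function(d)
    length(d$pr_values), integer(1))), levels = labels)

  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  anova_df <- data.frame(
    F = tab["group", "F value"], df1 = tab["group", "Df"],
    df2 = tab["Residuals", "Df"], p = tab["group", "Pr(>F)"]
  )

  pairs <- utils::combn(length(dists), 2L, simplify = FALSE)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- stats::t.test(dists[[pr[1]]]$pr_values, dists[[pr[2]]]$pr_values)
    data.frame(
      group1 = labels[pr[1]], group2 = labels[pr[2]],
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
    )
  }))
  posthoc$p_bonferroni <- pmin(posthoc$p * length(pairs), 1)

  group_stats <- data.frame(
    condition = labels,
    mean_pr = vapply(dists, function(d) mean(d$pr_values), numeric(1)),
    sd_pr = vapply(dists, function(d) stats::sd(d$pr_values), numeric(1)),
    n = vapply(dists, function(d) length(d$pr_values), integer(1))
  )
  list(anova = anova_df, posthoc = posthoc, group_stats = group_stats)
}
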
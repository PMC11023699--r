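# Drug-minus-placebo behavioral matrices, behavioral PCA with a
# column-wise permutation null, PANSS subscale scoring, and the
# Pitman-Morgan paired variance test.

#' Assemble the drug-minus-placebo behavioral matrix
#'
#' Elementwise `drug - placebo`; cells missing in either condition are, by
#' default, imputed with the column mean over the observed differences
#' (imputation therefore never changes a column's mean).
#'
#' @param drug,placebo subjects x items matrices with identical dimnames.
#' @param impute impute missing difference cells (default `TRUE`).
#' @return subjects x items difference matrix.
#' @export
assemble_delta_behavior <- function(drug, placebo, impute = TRUE) {
  drug <- as.matrix(drug)
  placebo <- as.matrix(placebo)
  if (!identical(dim(drug), dim(placebo)))
    stop("drug and placebo must cover the same subjects and items")
  delta <- drug - placebo
  if (impute && anyNA(delta)) {
    for (j in seq_len(ncol(delta))) {
      nas <- is.na(delta[, j])
      if (all(nas))
        stop(sprintf("column %d is entirely missing", j))
      if (any(nas)) delta[nas, j] <- mean(delta[!nas, j])
    }
  }
  delta
}

#' PCA of the behavioral matrix
#'
#' Items are standardized (centered, unit variance across participants)
#' before the SVD -- behavioral items live on heterogeneous scales, unlike
#' parcels of a single map. Otherwise identical to [fit_delta_pca].
#'
#' @param b subjects x items matrix, no missing values.
#' @return a `pca_solution`.
#' @export
fit_behavior_pca <- function(b) {
  b <- as.matrix(b)
  sds <- apply(b, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(b)[sds == 0] %||% which(sds == 0)
    stop(sprintf("zero-variance item(s): %s", paste(bad, collapse = ", ")))
  }
  fit_delta_pca(b, scale = TRUE)
}

#' Permutation significance of behavioral components (column shuffling)
#'
#' Each permutation independently shuffles participant order within every
#' item column (breaking inter-item covariance while preserving marginals),
#' refits the standardized PCA, and records the variance fraction at each
#' rank; `p_k = (1 + #{>= observed}) / (n_perm + 1)`. The retained set is
#' the leading run of components with `p < alpha` (retention stops at the
#' first non-significant rank, which keeps the null retention error at
#' `alpha`).
#'
#' @param b subjects x items matrix.
#' @param n_perm permutations (default 5000).
#' @param seed integer seed.
#' @param alpha retention threshold (default 0.05).
#' @return a `pca_solution` with `perm_p`, `significant`, `n_retained`.
#' @export
permute_behavior_significance <- function(b, n_perm = 5000L, seed = 1L,
                                          alpha = 0.05) {
  b <- as.matrix(b)
  stopifnot(is_count(n_perm), n_perm >= 100L)
  sol <- fit_behavior_pca(b)
  k <- length(sol$var_frac)
  obs <- sol$var_frac
  counts <- integer(k)
  n <- nrow(b)
  with_seed(seed, {
    for (it in seq_len(n_perm)) {
      perm <- apply(b, 2L, sample)
      xp <- scale(perm)
      vf <- varfrac_by_rank(xp)[seq_len(k)]
      counts <- counts + (vf >= obs)
    }
  })
  sol$perm_p <- (1 + counts) / (n_perm + 1)
  sol$significant <- leading_run(sol$perm_p < alpha)
  sol$n_retained <- sum(sol$significant)
  sol
}

#' PANSS item-to-subscale configurations
#'
#' The three-factor scheme is the conventional PANSS split: Positive (7
#' items P1-P7), Negative (7 items N1-N7), General Psychopathology (16
#' items G1-G16). The five-factor alternative partitions the same 30 items
#' into Positive, Negative, Disorganization, Excitement and Emotional
#' Distress. Configurations are shipped as YAML under
#' `inst/extdata/subscales/` and parsed here; the cognition score is not a
#' PANSS item and belongs to no subscale.
#'
#' @param scheme `"three_factor"` or `"five_factor"`.
#' @return named list mapping subscale name to item names.
#' @export
panss_subscales <- function(scheme = c("three_factor", "five_factor")) {
  scheme <- match.arg(scheme)
  path <- system.file("extdata", "subscales", paste0(scheme, ".yaml"),
                      package = "deltagbc")
  if (!nzchar(path)) stop("subscale configuration not found")
  yaml::read_yaml(path)
}

#' Default behavioral item names: 30 PANSS items plus a cognition score
#' @return character vector of length 31.
#' @export
panss_item_names <- function() {
  c(paste0("P", 1:7), paste0("N", 1:7), paste0("G", 1:16), "cognition")
}

#' PANSS subscale scores
#'
#' Subscale score = sum of the member items' values. The configuration
#' must cover every PANSS item in the matrix exactly once; non-PANSS
#' columns (e.g. cognition) are ignored.
#'
#' @param b subjects x items matrix with item column names.
#' @param scheme subscale scheme, see [panss_subscales]; alternatively a
#'   named list mapping subscales to item names.
#' @return subjects x subscales matrix.
#' @export
subscale_scores <- function(b, scheme = "three_factor") {
  b <- as.matrix(b)
  if (is.null(colnames(b))) stop("behavior matrix needs item column names")
  config <- if (is.list(scheme)) scheme else panss_subscales(scheme)
  members <- unlist(config, use.names = FALSE)
  if (anyDuplicated(members))
    stop("subscale configuration assigns an item twice")
  missing <- setdiff(members, colnames(b))
  if (length(missing))
    stop(sprintf("configuration item(s) missing from matrix: %s",
                 paste(missing, collapse = ", ")))
  panss_cols <- grep("^(P|N|G)[0-9]+$", colnames(b), value = TRUE)
  uncovered <- setdiff(panss_cols, members)
  if (length(uncovered))
    stop(sprintf("PANSS item(s) not covered by the configuration: %s",
                 paste(uncovered, collapse = ", ")))
  out <- vapply(config, function(items)
    rowSums(b[, items, drop = FALSE]), numeric(nrow(b)))
  rownames(out) <- rownames(b)
  out
}

#' Pitman-Morgan test for equality of variances of paired samples
#'
#' With `F = var(x) / var(y)` and `r = cor(x, y)`,
#' `t = (F - 1) * sqrt(S - 2) / (2 * sqrt(F * (1 - r^2)))` on `S - 2`
#' degrees of freedom (two-tailed). At `r -> +/-1` with unequal variances
#' the statistic diverges and the p-value is reported as 0; equal
#' variances give `t = 0` through the `F - 1` numerator.
#'
#' @param x,y paired numeric vectors, `S >= 4`.
#' @return list: `t`, `df`, `p`.
#' @export
pitman_morgan <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  s <- length(x)
  stopifnot(length(y) == s, s >= 4L)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("degenerate input: zero variance")
  f <- vx / vy
  r <- stats::cor(x, y)
  df <- s - 2L
  if (f == 1) {
    t <- 0
  } else if (abs(r) >= 1 - 1e-12) {
    t <- sign(f - 1) * Inf
  } else {
    t <- (f - 1) * sqrt(s - 2) / (2 * sqrt(f * (1 - r^2)))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
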
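# PCA of per-subject drug-minus-placebo GBC maps with a parcel-shuffle
# permutation null, Z-scored component maps and network summaries.

#' PCA across subjects' drug-minus-placebo GBC maps
#'
#' Features (parcels) are centered across subjects and, by default, not
#' variance-scaled; the solution is obtained by SVD of the centered matrix
#' with `K = min(subjects - 1, parcels)` components retained. Component
#' signs are fixed deterministically: each loading is flipped so that its
#' correlation with the group-mean map is non-negative (a zero-correlation
#' tie falls back to making the largest-magnitude parcel loading
#' positive).
#'
#' @param maps subjects x parcels numeric matrix, no missing values.
#' @param scale standardize parcels to unit variance before the SVD
#'   (default `FALSE`; behavioral PCA sets this).
#' @return a `pca_solution`: `loadings` (parcels x K, orthonormal),
#'   `scores` (subjects x K, `scores = centered_maps %*% loadings`),
#'   `eigenvalues`, `var_frac`, `mean_map`, and (after
#'   [permutation_significance]) `perm_p` / `significant`.
#' @export
fit_delta_pca <- function(maps, scale = FALSE) {
  maps <- as.matrix(maps)
  s <- nrow(maps)
  p <- ncol(maps)
  stopifnot(s >= 3L)
  if (anyNA(maps)) stop("maps must not contain missing values")
  mean_map <- colMeans(maps)
  x <- scale(maps, center = TRUE, scale = scale)
  if (all(abs(x) < 1e-13))
    stop("degenerate input: all maps identical after centering")
  k <- min(s - 1L, p)
  sv <- svd(x, nu = k, nv = k)
  eigenvalues <- sv$d[seq_len(k)]^2 / (s - 1)
  total_var <- sum(sv$d^2) / (s - 1)
  loadings <- sv$v
  scores <- x %*% loadings

  # deterministic sign convention
  for (j in seq_len(k)) {
    r <- suppressWarnings(stats::cor(loadings[, j], mean_map))
    flip <- if (is.finite(r) && abs(r) > 1e-12) r < 0
    else loadings[which.max(abs(loadings[, j])), j] < 0
    if (flip) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- colnames(maps)
  rownames(scores) <- rownames(maps)

  structure(
    list(loadings = loadings, scores = scores, eigenvalues = eigenvalues,
         var_frac = eigenvalues / total_var, mean_map = mean_map,
         scale = scale, perm_p = NULL, significant = NULL),
    class = "pca_solution"
  )
}

#' @export
print.pca_solution <- function(x, ...) {
  k_show <- min(5L, length(x$var_frac))
  cat(sprintf("pca_solution: %d components (%d subjects x %d features)\n",
              length(x$eigenvalues), nrow(x$scores), nrow(x$loadings)))
  cat("  var_frac:", paste(sprintf("%.3f", x$var_frac[seq_len(k_show)]),
                           collapse = " "), "...\n")
  if (!is.null(x$perm_p))
    cat(sprintf("  %d significant component(s) by permutation\n",
                sum(x$significant)))
  invisible(x)
}

# Variance fraction per component rank of a centered (optionally scaled)
# matrix, via the eigenvalues of the subject-by-subject Gram matrix --
# much cheaper than a full SVD when subjects << parcels.
varfrac_by_rank <- function(x) {
  g <- tcrossprod(x)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

#' Permutation significance of PCA components (parcel shuffling)
#'
#' For each permutation every subject's parcel vector is shuffled
#' independently (destroying the shared spatial structure while preserving
#' each subject's value distribution), the PCA is refit, and the variance
#' fraction at each component rank recorded. The p-value at rank k is
#' `(1 + #{permuted var_frac_k >= observed var_frac_k}) / (n_perm + 1)`;
#' The retained set is the leading run of components with `p < alpha`
#' (retention stops at the first non-significant rank): significant
#' components of a PCA are a contiguous top set, and marking isolated
#' deeper ranks would inflate the family-wise retention error far above
#' `alpha` under the null.
#'
#' @param maps subjects x parcels matrix.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @param alpha retention threshold (default 0.05).
#' @param scale forwarded to the PCA (default `FALSE`).
#' @return a `pca_solution` (as [fit_delta_pca]) with `perm_p`,
#'   `significant`, and `n_retained` filled in.
#' @export
permutation_significance <- function(maps, n_perm = 1000L, seed = 1L,
                                     alpha = 0.05, scale = FALSE) {
  maps <- as.matrix(maps)
  stopifnot(is_count(n_perm), n_perm >= 100L)
  sol <- fit_delta_pca(maps, scale = scale)
  k <- length(sol$var_frac)
  obs <- sol$var_frac
  counts <- integer(k)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- t(apply(maps, 1L, sample))
      xp <- scale(perm, center = TRUE, scale = scale)
      vf <- varfrac_by_rank(xp)[seq_len(k)]
      counts <- counts + (vf >= obs)
    }
  })
  sol$perm_p <- (1 + counts) / (n_perm + 1)
  sol$significant <- leading_run(sol$perm_p < alpha)
  sol$n_retained <- sum(sol$significant)
  sol
}

# TRUE for the leading run of TRUEs, FALSE afterwards.
leading_run <- function(flag) {
  out <- cumprod(flag) > 0
  as.logical(out)
}

#' Z-scored component map
#'
#' Loading column `k` standardized to mean 0, sd 1 across parcels (the
#' conventional display scale for component maps).
#'
#' @param solution a `pca_solution`.
#' @param k component index.
#' @return per-parcel numeric vector.
#' @export
pc_zmap <- function(solution, k = 1L) {
  stopifnot(inherits(solution, "pca_solution"),
            k >= 1L, k <= ncol(solution$loadings))
  standardize(solution$loadings[, k])
}

#' Correlate component maps with the group-mean map
#'
#' Pearson correlation (across parcels) between each selected component
#' map and the mean drug-minus-placebo map, with Bonferroni-adjusted
#' p-values. When a centroid distance matrix is supplied the p-values come
#' from the spatial-autocorrelation-preserving surrogate-map test
#' ([surrogate_correlation_test]); otherwise the parametric correlation
#' test is used.
#'
#' @param solution a `pca_solution`.
#' @param mean_map per-parcel mean map (defaults to the one stored in the
#'   solution).
#' @param components indices to test (defaults to the significant set, or
#'   all components when significance has not been run).
#' @param dist optional parcels x parcels distance matrix (enables the
#'   surrogate test).
#' @param hemi optional hemisphere labels forwarded to
#'   [generate_surrogates].
#' @param m surrogates per component when `dist` is given.
#' @param seed seed for surrogate generation.
#' @return data frame: component, r, p, p_bonferroni.
#' @export
correlate_with_mean <- function(solution, mean_map = NULL, components = NULL,
                                dist = NULL, hemi = NULL, m = 1000L,
                                seed = 1L) {
  stopifnot(inherits(solution, "pca_solution"))
  if (is.null(mean_map)) mean_map <- solution$mean_map
  if (is.null(components)) {
    components <- if (!is.null(solution$significant) &&
                      any(solution$significant))
      which(solution$significant)
    else seq_along(solution$var_frac)
  }
  res <- lapply(components, function(k) {
    zmap <- pc_zmap(solution, k)
    if (is.null(dist)) {
      ct <- stats::cor.test(zmap, mean_map)
      c(r = unname(ct$estimate), p = ct$p.value)
    } else {
      ens <- generate_surrogates(zmap, dist, m = m, seed = seed + k,
                                 hemi = hemi)
      st <- surrogate_correlation_test(zmap, mean_map, ens)
      c(r = st$r, p = st$p)
    }
  })
  res <- do.call(rbind, res)
  data.frame(
    component = components, r = res[, "r"], p = res[, "p"],
    p_bonferroni = pmin(res[, "p"] * length(components), 1)
  )
}

#' Per-network summary of a component map and the association-vs-sensory
#' contrast
#'
#' Mean Z per network, plus a label-permutation test of the mean difference
#' between association and sensory parcels (two-tailed). Parcels within a
#' network are spatially dependent, so a permutation of the class labels is
#' used rather than a parametric two-sample test.
#'
#' @param zmap per-parcel numeric map.
#' @param atlas a `parcel_atlas`.
#' @param n_perm label permutations (default 10000).
#' @param seed integer seed.
#' @return list: `network_means` (data frame), `contrast` (mean difference
#'   association - sensory), `p` (two-tailed permutation p).
#' @export
network_summary <- function(zmap, atlas, n_perm = 10000L, seed = 1L) {
  validate_atlas(atlas)
  zmap <- as.numeric(zmap)
  stopifnot(length(zmap) == nrow(atlas))
  tab <- table(atlas$klass)
  if (any(tab < 2L)) stop("each klass needs at least 2 parcels")
  network_means <- stats::aggregate(
    list(mean_z = zmap), by = list(network = atlas$network), FUN = mean
  )
  is_assoc <- atlas$klass == "association"
  obs <- mean(zmap[is_assoc]) - mean(zmap[!is_assoc])
  n_assoc <- sum(is_assoc)
  p <- with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample(length(zmap), n_assoc)
      d <- mean(zmap[idx]) - mean(zmap[-idx])
      if (abs(d) >= abs(obs)) exceed <- exceed + 1L
    }
    (1 + exceed) / (n_perm + 1)
  })
  list(network_means = network_means, contrast = obs, p = p)
}
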
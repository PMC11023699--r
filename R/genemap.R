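# Spatial-autocorrelation-preserving surrogate-map significance testing
# for map-to-map correlations, with FDR control and per-subject gene
# association profiles.

#' Binned empirical variogram of a parcel map
#'
#' `gamma(h) = 0.5 * mean over pairs in bin h of (v_i - v_j)^2`, with
#' equal-count bins over the pairwise distances. The variogram is the
#' spatial-autocorrelation fingerprint that surrogate maps are matched to.
#'
#' @param map per-parcel numeric vector.
#' @param dist symmetric parcels x parcels distance matrix, zero diagonal.
#' @param n_bins number of equal-count distance bins (default 25; reduced
#'   with a warning when there are fewer distinct distances).
#' @return list: `centers` (mean pair distance per bin), `gamma`.
#' @export
empirical_variogram <- function(map, dist, n_bins = 25L) {
  map <- as.numeric(map)
  dist <- as.matrix(dist)
  p <- length(map)
  stopifnot(nrow(dist) == p, ncol(dist) == p,
            max(abs(dist - t(dist))) < 1e-10, all(diag(dist) == 0))
  setup <- vgm_setup(dist, n_bins = n_bins)
  g <- vgm_gamma(matrix(map, ncol = 1L), setup)
  list(centers = setup$centers, gamma = as.numeric(g))
}

# Precompute pair indices, bin assignment and bin centers so that the
# variogram of many maps can be evaluated cheaply. `n_pair_samples`
# optionally subsamples the pair set (seeded), which is what makes large
# surrogate ensembles affordable.
vgm_setup <- function(dist, n_bins = 25L, n_pair_samples = Inf, seed = 1L) {
  p <- nrow(dist)
  idx <- which(upper.tri(dist))
  if (is.finite(n_pair_samples) && n_pair_samples < length(idx))
    idx <- with_seed(seed, sample(idx, n_pair_samples))
  d <- dist[idx]
  i <- ((idx - 1L) %% p) + 1L   # row index of upper.tri element
  j <- ((idx - 1L) %/% p) + 1L  # column index
  n_distinct <- length(unique(d))
  if (n_distinct < n_bins) {
    warning(sprintf("only %d distinct distances; reducing bins from %d",
                    n_distinct, n_bins))
    n_bins <- n_distinct
  }
  breaks <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(d, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  centers <- as.numeric(tapply(d, bin, mean))
  counts <- as.integer(table(bin))
  list(i = i, j = j, bin = bin, centers = centers, counts = counts,
       n_bins = length(centers))
}

# Binned variogram for every column of a parcels x m matrix; returns
# n_bins x m. Chunked over columns to bound memory.
vgm_gamma <- function(x, setup, chunk = 200L) {
  x <- as.matrix(x)
  m <- ncol(x)
  out <- matrix(NA_real_, setup$n_bins, m)
  for (start in seq(1L, m, by = chunk)) {
    cols <- start:min(start + chunk - 1L, m)
    sq <- (x[setup$i, cols, drop = FALSE] - x[setup$j, cols, drop = FALSE])^2
    out[, cols] <- 0.5 * rowsum(sq, setup$bin) / setup$counts
  }
  out
}

# Row-normalized k-nearest-neighbour exponential smoothing kernels, one
# sparse matrix per k. The kernel width at each parcel is its distance to
# the k-th neighbour.
knn_smoothers <- function(dist, knn) {
  p <- nrow(dist)
  knn <- sort(unique(pmin(knn, p - 1L)))
  lapply(knn, function(k) {
    ii <- jj <- ww <- vector("list", p)
    for (r in seq_len(p)) {
      ord <- order(dist[r, ])[2:(k + 1L)]  # nearest k, excluding self
      d <- dist[r, ord]
      w <- exp(-d / d[k])
      ii[[r]] <- rep(r, k)
      jj[[r]] <- ord
      ww[[r]] <- w / sum(w)
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                         dims = c(p, p))
  })
}

#' Generate spatial-autocorrelation-matched surrogate maps
#'
#' Each surrogate starts from a random permutation of the target's values,
#' which destroys the spatial structure while preserving the value
#' distribution. The permuted map is then smoothed with a k-nearest-
#' neighbour exponential distance-decay kernel for each k in `knn`; each
#' smoothed candidate is affine-rescaled to minimize the squared error
#' between its binned variogram and the target's (scaling a map by `a`
#' scales its variogram by `a^2`); and the candidate whose realized
#' variogram has the smallest squared error to the target's is kept (the
#' unsmoothed permutation itself is always in the candidate set, so a
#' surrogate is never a worse variogram match than a plain permutation). When hemisphere labels are supplied surrogates are generated per
#' hemisphere and merged, mirroring how cortical maps are handled.
#'
#' @param target per-parcel numeric map.
#' @param dist parcels x parcels distance matrix.
#' @param m number of surrogates (>= 1).
#' @param seed integer seed.
#' @param hemi optional per-parcel hemisphere labels; `NULL` disables the
#'   per-hemisphere split.
#' @param knn candidate neighbourhood sizes (default `c(5, 10, 20, 50,
#'   100)`, truncated to `parcels - 1`).
#' @param n_bins variogram bins (default 25).
#' @param n_pair_samples pairs used for variogram evaluation (default
#'   10000; the full pair set when smaller).
#' @return a `surrogate_ensemble`: `maps` (m x parcels), `seed`,
#'   `variogram_sse` (per surrogate), `sse_permutation` (per-surrogate SSE
#'   of the unsmoothed permutation, the naive baseline).
#' @export
generate_surrogates <- function(target, dist, m = 1000L, seed = 1L,
                                hemi = NULL, knn = c(5L, 10L, 20L, 50L, 100L),
                                n_bins = 25L, n_pair_samples = 10000L) {
  target <- as.numeric(target)
  dist <- as.matrix(dist)
  p <- length(target)
  stopifnot(nrow(dist) == p, is_count(m))

  if (!is.null(hemi)) {
    stopifnot(length(hemi) == p)
    sides <- split(seq_len(p), hemi)
    if (any(lengths(sides) < 2L)) {
      warning("a hemisphere has fewer than 2 parcels; generating whole-map surrogates")
      hemi <- NULL
    }
  }
  groups <- if (is.null(hemi)) list(seq_len(p)) else sides

  maps <- matrix(NA_real_, m, p)
  sse <- matrix(0, m, length(groups))
  sse_perm <- matrix(0, m, length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    part <- surrogate_block(target[idx], dist[idx, idx, drop = FALSE], m,
                            seed = seed + 7919L * gi, knn = knn,
                            n_bins = n_bins,
                            n_pair_samples = n_pair_samples)
    maps[, idx] <- part$maps
    sse[, gi] <- part$sse
    sse_perm[, gi] <- part$sse_perm
  }
  structure(
    list(maps = maps, seed = seed, variogram_sse = rowSums(sse),
         sse_permutation = rowSums(sse_perm), n_surrogates = m),
    class = "surrogate_ensemble"
  )
}

# Surrogates for one block of parcels (a hemisphere or the whole map).
# Each smoothed candidate is affine-rescaled, a * candidate + b: scaling a
# map by `a` scales its variogram by a^2 (offsets leave it unchanged), so
# the least-squares match to the target's binned variogram is
# a^2 = sum(gamma_s * gamma_t) / sum(gamma_s^2). A nugget/white-noise term
# is deliberately NOT added: it would dilute the surrogates' large-scale
# spatial power, which is exactly what the null distribution of map-to-map
# correlations is most sensitive to (adding one measurably narrows the
# null and inflates small p-values in calibration runs).
surrogate_block <- function(target, dist, m, seed, knn, n_bins,
                            n_pair_samples) {
  p <- length(target)
  setup <- vgm_setup(dist, n_bins = n_bins, n_pair_samples = n_pair_samples,
                     seed = seed)
  gamma_t <- as.numeric(vgm_gamma(matrix(target, ncol = 1L), setup))
  smoothers <- knn_smoothers(dist, knn)

  with_seed(seed, {
    perms <- vapply(seq_len(m), function(b) target[sample(p)],
                    numeric(p))                      # p x m
    gamma_perm <- vgm_gamma(perms, setup)
    sse_perm <- colSums((gamma_perm - gamma_t)^2)

    best_maps <- perms
    best_sse <- sse_perm
    for (w in smoothers) {
      sm <- as.matrix(w %*% perms)
      # standardize candidates so the rescale factor is well conditioned
      sm <- scale(sm)
      bad <- !is.finite(colSums(sm))
      if (any(bad)) sm[, bad] <- 0
      gamma_s <- vgm_gamma(sm, setup)
      a2 <- pmax(colSums(gamma_s * gamma_t), 0) /
        pmax(colSums(gamma_s^2), 1e-300)
      cand <- sweep(sm, 2L, sqrt(a2), "*")
      gamma_c <- vgm_gamma(cand, setup)
      sse_c <- colSums((gamma_c - gamma_t)^2)
      take <- sse_c < best_sse
      if (any(take)) {
        best_maps[, take] <- cand[, take]
        best_sse[take] <- sse_c[take]
      }
    }
    # variograms are translation invariant; pin every surrogate to the
    # target's block mean so hemisphere merging cannot introduce piecewise
    # offsets (keeps the test affine-equivariant in the target)
    best_maps <- sweep(best_maps, 2L, mean(target) - colMeans(best_maps), "+")
    list(maps = t(best_maps), sse = best_sse, sse_perm = sse_perm)
  })
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "surrogate_ensemble: %d maps x %d parcels (median variogram SSE ratio %.3f)\n",
    nrow(x$maps), ncol(x$maps),
    stats::median(x$variogram_sse / pmax(x$sse_permutation, 1e-300))
  ))
  invisible(x)
}

#' Surrogate-map significance of a map-to-map correlation
#'
#' The observed Pearson correlation between the target and the comparison
#' map is ranked against the correlations between the comparison map and
#' each member of a surrogate ensemble built from the target, giving a
#' permutation p-value that respects the target's spatial autocorrelation.
#' Two-tailed on `|r|`; the p floor is `1 / (m + 1)`.
#'
#' @param target per-parcel map the ensemble was generated from.
#' @param comparison_map per-parcel map to test (e.g. a gene-expression
#'   map); missing parcels are dropped pairwise.
#' @param ensemble a `surrogate_ensemble` from [generate_surrogates].
#' @return list: `r` (observed), `p` (two-tailed permutation p),
#'   `r_null` (the simulated correlations).
#' @export
surrogate_correlation_test <- function(target, comparison_map, ensemble) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  target <- as.numeric(target)
  comparison_map <- as.numeric(comparison_map)
  stopifnot(length(target) == length(comparison_map),
            length(target) == ncol(ensemble$maps))
  ok <- is.finite(target) & is.finite(comparison_map)
  if (sum(ok) < 30L) stop("fewer than 30 shared parcels")
  r_obs <- stats::cor(target[ok], comparison_map[ok])
  r_null <- cor_vec_mat(comparison_map[ok], t(ensemble$maps[, ok, drop = FALSE]))
  m <- length(r_null)
  p <- (1 + sum(abs(r_null) >= abs(r_obs), na.rm = TRUE)) / (m + 1)
  list(r = r_obs, p = p, r_null = r_null)
}

#' Screen gene maps by cortical differential stability
#'
#' Genes whose differential-stability value lies in the exclusion band
#' `|DS| <= ds_band` are removed: near-zero DS means the cortical
#' expression topography is not reproducible across donors.
#'
#' @param genes data frame with columns `gene` and `differential_stability`
#'   (or a named numeric vector of DS values).
#' @param ds_band half-width of the exclusion band (default 0.1).
#' @return the retained subset, with attribute `excluded` listing dropped
#'   genes.
#' @export
screen_genes <- function(genes, ds_band = 0.1) {
  if (is.numeric(genes))
    genes <- data.frame(gene = names(genes), differential_stability = genes,
                        stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "differential_stability") %in% names(genes)))
  keep <- abs(genes$differential_stability) > ds_band
  out <- genes[keep, , drop = FALSE]
  attr(out, "excluded") <- genes$gene[!keep]
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values; a thin, named wrapper so the module surface mirrors
#' the analysis pipeline.
#'
#' @param pvals p-values in (0, 1].
#' @return q-values, elementwise >= p.
#' @export
fdr_correct <- function(pvals) {
  stopifnot(all(pvals > 0), all(pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Per-subject gene-expression association profiles
#'
#' For each subject, the correlation of their drug-minus-placebo GBC map
#' with each gene-expression map, with significance from a surrogate
#' ensemble generated from that subject's own map, and a sign-pattern
#' label (the sign pair over the first two gene maps, e.g. `+-` for a
#' positive SST and negative PVALB association).
#'
#' @param delta_maps subjects x parcels matrix.
#' @param gene_maps named list (>= 2) of per-parcel gene maps.
#' @param dist parcels x parcels distance matrix.
#' @param hemi optional hemisphere labels.
#' @param m_per_subject surrogates per subject (default 1000; `0` skips
#'   the significance test and returns correlations only).
#' @param seed integer seed.
#' @return data frame with per-gene `r_<gene>` and `p_<gene>` columns, a
#'   `pattern` label per subject, and attribute `pattern_counts`.
#' @export
subject_gene_profile <- function(delta_maps, gene_maps, dist = NULL,
                                 hemi = NULL, m_per_subject = 1000L,
                                 seed = 1L) {
  delta_maps <- as.matrix(delta_maps)
  stopifnot(is.list(gene_maps), length(gene_maps) >= 2L,
            !is.null(names(gene_maps)))
  if (m_per_subject > 0 && is.null(dist))
    stop("dist is required when m_per_subject > 0")
  s <- nrow(delta_maps)
  gene_names <- names(gene_maps)
  r_mat <- matrix(NA_real_, s, length(gene_maps),
                  dimnames = list(rownames(delta_maps), gene_names))
  p_mat <- r_mat
  for (i in seq_len(s)) {
    target <- delta_maps[i, ]
    ens <- if (m_per_subject > 0)
      generate_surrogates(target, dist, m = m_per_subject,
                          seed = seed + i, hemi = hemi)
    for (g in seq_along(gene_maps)) {
      if (m_per_subject > 0) {
        st <- surrogate_correlation_test(target, gene_maps[[g]], ens)
        r_mat[i, g] <- st$r
        p_mat[i, g] <- st$p
      } else {
        r_mat[i, g] <- stats::cor(target, gene_maps[[g]])
      }
    }
  }
  pattern <- apply(r_mat[, 1:2, drop = FALSE], 1L, function(r)
    paste(ifelse(r >= 0, "+", "-"), collapse = ""))
  out <- data.frame(subject = rownames(delta_maps) %||% seq_len(s),
                    stringsAsFactors = FALSE)
  for (g in seq_along(gene_maps)) {
    out[[paste0("r_", gene_names[g])]] <- r_mat[, g]
    if (m_per_subject > 0) out[[paste0("p_", gene_names[g])]] <- p_mat[, g]
  }
  out$pattern <- pattern
  attr(out, "pattern_counts") <- table(pattern)
  out
}
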
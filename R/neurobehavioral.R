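# Mass-univariate mapping of behavioral scores onto drug-minus-placebo
# GBC maps, family-wise-error control by permutation, single-subject
# projections and the SST-PVALB coupling analysis.

#' Mass-univariate regression of GBC on a behavioral score
#'
#' Per parcel, the simple OLS slope of drug-minus-placebo GBC on the
#' standardized behavioral score (`slope = cov(score, parcel) /
#' var(score)`); slopes are Z-scored across parcels into the coefficient
#' map. Standardizing the score makes coefficient maps comparable across
#' behavioral variables.
#'
#' @param delta_maps subjects x parcels matrix (`S >= 5`).
#' @param score per-subject behavioral score with nonzero variance.
#' @param score_name label carried on the result.
#' @return a `neurobehav_map`: `coef_z` (Z-scored across parcels),
#'   `coef_raw`, `score_name`; `p_corrected` is filled by
#'   [permutation_correct].
#' @export
mass_univariate_map <- function(delta_maps, score, score_name = "score") {
  delta_maps <- as.matrix(delta_maps)
  s <- nrow(delta_maps)
  stopifnot(s >= 5L, length(score) == s)
  if (stats::sd(score) == 0) stop("score has zero variance")
  z <- standardize(score)
  slopes <- as.numeric(crossprod(z, scale(delta_maps, scale = FALSE))) / (s - 1)
  structure(
    list(coef_raw = slopes, coef_z = standardize(slopes),
         p_corrected = NULL, score_name = score_name, n_perm = 0L),
    class = "neurobehav_map"
  )
}

#' @export
print.neurobehav_map <- function(x, ...) {
  cat(sprintf("neurobehav_map (%s): %d parcels", x$score_name,
              length(x$coef_z)))
  if (!is.null(x$p_corrected))
    cat(sprintf(", %d parcel(s) with corrected p < 0.05 (%d permutations)",
                sum(x$p_corrected < 0.05), x$n_perm))
  cat("\n")
  invisible(x)
}

# Per-parcel correlations for a matrix of permuted scores: rows = perms.
perm_cor_matrix <- function(score_perms, maps_c, maps_ss) {
  zc <- scale(t(score_perms), scale = FALSE)  # subjects x perms, centered
  num <- crossprod(zc, maps_c)                # perms x parcels
  den <- outer(sqrt(colSums(zc^2)), maps_ss)
  num / den
}

#' Permutation family-wise-error correction of a mass-univariate map
#'
#' The score vector is permuted across subjects `n_perm` times and the
#' per-parcel statistic (the absolute parcel-score correlation, a pivotal
#' equivalent of the regression t) recomputed. `max_stat` compares each
#' observed statistic with the permutation distribution of the maximum
#' over parcels (exactly valid, assumption-light); `tfce` first enhances
#' the statistic map by threshold-free cluster enhancement (E = 0.5,
#' H = 2) over a parcel adjacency graph before taking the maximum.
#'
#' @param delta_maps subjects x parcels matrix.
#' @param score per-subject behavioral score.
#' @param n_perm permutations (default 5000).
#' @param method `"max_stat"` (default) or `"tfce"`.
#' @param adjacency parcels x parcels logical/0-1 adjacency matrix,
#'   required for TFCE (see [knn_adjacency]).
#' @param seed integer seed.
#' @return a `neurobehav_map` with `p_corrected` per parcel.
#' @export
permutation_correct <- function(delta_maps, score, n_perm = 5000L,
                                method = c("max_stat", "tfce"),
                                adjacency = NULL, seed = 1L) {
  method <- match.arg(method)
  delta_maps <- as.matrix(delta_maps)
  s <- nrow(delta_maps)
  p <- ncol(delta_maps)
  stopifnot(length(score) == s, is_count(n_perm))
  if (method == "tfce") {
    if (is.null(adjacency)) stop("tfce requires a parcel adjacency")
    adjacency <- as.matrix(adjacency) != 0
    stopifnot(nrow(adjacency) == p, ncol(adjacency) == p)
    nbrs <- apply(adjacency, 1L, which, simplify = FALSE)
    if (n_components(nbrs) > 1L)
      warning("adjacency is disconnected; components are handled independently")
  }

  maps_c <- scale(delta_maps, scale = FALSE)
  maps_ss <- sqrt(colSums(maps_c^2))
  r_obs <- as.numeric(cor_vec_mat(score, delta_maps))
  t_obs <- r_to_t(r_obs, s)
  stat_obs <- if (method == "max_stat") abs(r_obs)
  else tfce_enhance(t_obs, nbrs)

  exceed <- integer(p)
  with_seed(seed, {
    chunk <- 250L
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      perms <- t(vapply(seq_len(nb), function(b) sample(score), numeric(s)))
      r_perm <- perm_cor_matrix(perms, maps_c, maps_ss)
      max_perm <- if (method == "max_stat") {
        apply(abs(r_perm), 1L, max)
      } else {
        t_perm <- r_to_t(r_perm, s)
        vapply(seq_len(nb), function(b)
          max(tfce_enhance(t_perm[b, ], nbrs)), numeric(1))
      }
      exceed <- exceed + vapply(stat_obs, function(o)
        sum(max_perm >= o), numeric(1))
      done <- done + nb
    }
  })
  out <- mass_univariate_map(delta_maps, score)
  out$p_corrected <- (1 + exceed) / (n_perm + 1)
  out$n_perm <- as.integer(n_perm)
  out$method <- method
  out
}

r_to_t <- function(r, s) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  r * sqrt(s - 2) / sqrt(1 - r^2)
}

# Connected components of a neighbour-list graph among `active` nodes.
graph_components <- function(nbrs, active) {
  comp <- integer(length(nbrs))
  cur <- 0L
  for (v in which(active)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (w in nbrs[[u]]) {
        if (active[w] && comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

n_components <- function(nbrs) {
  max(graph_components(nbrs, rep(TRUE, length(nbrs))))
}

# Threshold-free cluster enhancement of a signed statistic map over a
# parcel graph; positive and negative tails are enhanced separately.
tfce_enhance <- function(stat, nbrs, e = 0.5, h = 2, n_steps = 50L) {
  out <- numeric(length(stat))
  for (sgn in c(1, -1)) {
    x <- sgn * stat
    top <- max(x, 0)
    if (top <= 0) next
    dh <- top / n_steps
    heights <- seq(dh / 2, top, by = dh)
    for (hh in heights) {
      active <- x >= hh
      comp <- graph_components(nbrs, active)
      if (!any(active)) break
      sizes <- tabulate(comp)
      out[active] <- out[active] +
        sgn * (sizes[comp[active]]^e) * (hh^h) * dh
    }
  }
  out
}

#' k-nearest-neighbour parcel adjacency from atlas centroids
#'
#' @param atlas a `parcel_atlas`.
#' @param k neighbours per parcel (default 6); the graph is symmetrized by
#'   union.
#' @return parcels x parcels logical adjacency matrix.
#' @export
knn_adjacency <- function(atlas, k = 6L) {
  d <- atlas_dist(atlas)
  p <- nrow(d)
  adj <- matrix(FALSE, p, p)
  for (i in seq_len(p)) {
    ord <- order(d[i, ])[2:(k + 1L)]
    adj[i, ord] <- TRUE
  }
  adj | t(adj)
}

#' Project single subjects onto a reference map
#'
#' Pearson correlation of each subject's drug-minus-placebo map with the
#' reference map (typically a neuro-behavioral component map), Z-scored
#' across the cohort.
#'
#' @param delta_maps subjects x parcels matrix.
#' @param reference_map per-parcel map.
#' @return data frame: `subject`, `r`, `z` (mean 0, sd 1 across subjects;
#'   constant subject maps yield `NA` and are flagged).
#' @export
subject_projection <- function(delta_maps, reference_map) {
  delta_maps <- as.matrix(delta_maps)
  stopifnot(length(reference_map) == ncol(delta_maps))
  r <- as.numeric(cor_vec_mat(reference_map, t(delta_maps)))
  ok <- is.finite(r)
  z <- rep(NA_real_, length(r))
  z[ok] <- standardize(r[ok])
  data.frame(
    subject = rownames(delta_maps) %||% seq_len(nrow(delta_maps)),
    r = r, z = z, flagged = !ok, stringsAsFactors = FALSE
  )
}

#' Correlate per-subject SST-PVALB coupling with projection scores
#'
#' `d_s = r_SST - r_PVALB` per subject, correlated with the subjects'
#' projection Z-scores; parametric p and, optionally, a subject-label
#' permutation p.
#'
#' @param profiles a [subject_gene_profile] result (or any data frame
#'   whose first two `r_` columns hold the gene correlations).
#' @param projections a [subject_projection] result for the same subjects.
#' @param n_perm optional number of label permutations for a permutation p
#'   (0 disables).
#' @param seed integer seed.
#' @return list: `r`, `p`, optionally `p_perm`; degenerate inputs (a
#'   constant difference) are flagged with `degenerate = TRUE` and carry no
#'   numeric result.
#' @export
gene_coupling_correlation <- function(profiles, projections, n_perm = 0L,
                                      seed = 1L) {
  r_cols <- grep("^r_", names(profiles), value = TRUE)
  stopifnot(length(r_cols) >= 2L)
  d <- profiles[[r_cols[1L]]] - profiles[[r_cols[2L]]]
  z <- projections$z
  stopifnot(length(d) == length(z))
  ok <- is.finite(d) & is.finite(z)
  if (stats::sd(d[ok]) == 0 || stats::sd(z[ok]) == 0)
    return(list(degenerate = TRUE, r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(d[ok], z[ok])
  out <- list(degenerate = FALSE, r = unname(ct$estimate), p = ct$p.value)
  if (n_perm > 0) {
    obs <- abs(out$r)
    out$p_perm <- with_seed(seed, {
      exceed <- sum(vapply(seq_len(n_perm), function(b)
        abs(stats::cor(sample(d[ok]), z[ok])), numeric(1)) >= obs)
      (1 + exceed) / (n_perm + 1)
    })
  }
  out
}
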
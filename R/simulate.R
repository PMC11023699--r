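# Synthetic-data generators with planted ground truth. Every downstream
# stage of the pipeline has a recovery test against the quantities stored
# in the ground-truth container returned here.

#' Simulate per-subject drug-minus-placebo GBC maps with planted low-rank
#' structure
#'
#' Maps follow `map_s = mean_map + sum_k score_sk * sqrt(lambda_k) * u_k +
#' noise`, with orthonormal component maps `u_k` and iid standard-normal
#' subject scores. The first component is built to load oppositely on
#' association versus sensory parcels so that network-contrast tests have
#' planted signal.
#'
#' @param atlas a `parcel_atlas`.
#' @param n_subjects number of subjects (rows).
#' @param k number of planted components, `k < min(n_subjects, n_parcels)`.
#' @param eigenspectrum `k` strictly positive, non-increasing population
#'   eigenvalues of the planted covariance.
#' @param noise_sd standard deviation of the iid Gaussian parcel noise.
#' @param mean_map optional group-mean map added to every subject
#'   (defaults to zero).
#' @param whiten when `TRUE` the subject scores are centered and
#'   orthonormalized (then rescaled by `sqrt(n_subjects - 1)`) so the
#'   sample covariance of the signal part carries exactly the planted
#'   eigenspectrum rather than a Wishart-perturbed version of it; useful
#'   when a test needs the spectrum itself as ground truth.
#' @param seed integer seed.
#' @return list with `maps` (subjects x parcels) and `truth`
#'   (a `ground_truth` list holding `component_maps`, `subject_scores`,
#'   `eigenspectrum`, ...).
#' @export
simulate_delta_gbc <- function(atlas, n_subjects, k, eigenspectrum,
                               noise_sd = 1, mean_map = NULL,
                               whiten = FALSE, seed = 1L) {
  validate_atlas(atlas)
  p <- nrow(atlas)
  stopifnot(is_count(n_subjects), is_count(k))
  if (k >= min(n_subjects, p))
    stop("k must be smaller than min(n_subjects, n_parcels)")
  eigenspectrum <- as.numeric(eigenspectrum)
  if (length(eigenspectrum) != k)
    stop("eigenspectrum must have length k")
  if (any(eigenspectrum <= 0))
    stop("eigenspectrum entries must be strictly positive")
  if (is.unsorted(rev(eigenspectrum)))
    stop("eigenspectrum must be non-increasing")
  if (is.null(mean_map)) mean_map <- numeric(p)
  stopifnot(length(mean_map) == p, all(is.finite(mean_map)))

  with_seed(seed, {
    u <- planted_components(atlas, k)
    scores <- matrix(stats::rnorm(n_subjects * k), n_subjects, k)
    if (whiten) {
      scores <- scale(scores, scale = FALSE)
      scores <- qr.Q(qr(scores)) * sqrt(n_subjects - 1)
    }
    signal <- scores %*% (sqrt(eigenspectrum) * t(u))
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(n_subjects * p, sd = noise_sd), n_subjects, p)
    else 0
    maps <- sweep(signal, 2L, mean_map, "+") + noise
    dimnames(maps) <- list(
      paste0("sub", seq_len(n_subjects)), atlas$parcel_id
    )
    truth <- ground_truth(
      component_maps = u, subject_scores = scores,
      eigenspectrum = eigenspectrum, seed = seed
    )
    list(maps = maps, truth = truth)
  })
}

# Orthonormal planted component maps; the first is seeded with the
# association-vs-sensory contrast so k = 1 carries a network signal.
planted_components <- function(atlas, k) {
  p <- nrow(atlas)
  contrast <- ifelse(atlas$klass == "association", 1, -1)
  raw <- cbind(
    contrast + stats::rnorm(p, sd = 0.25),
    matrix(stats::rnorm(p * max(k - 1L, 0L)), p, max(k - 1L, 0L))
  )[, seq_len(k), drop = FALSE]
  u <- qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
  # qr.Q may flip signs; keep the first component positively aligned with
  # the association-vs-sensory contrast for interpretability.
  if (sum(u[, 1L] * contrast) < 0) u[, 1L] <- -u[, 1L]
  g <- crossprod(u)
  stopifnot(max(abs(g - diag(k))) < 1e-8)
  u
}

# Container for planted quantities; construction-time assertions enforce
# the invariants recovery tests rely on.
ground_truth <- function(component_maps = NULL, subject_scores = NULL,
                         eigenspectrum = NULL, behavior_coupling = NULL,
                         gene_target_corr = NULL, flagged_frames = NULL,
                         seed = NA_integer_) {
  if (!is.null(component_maps)) {
    g <- crossprod(component_maps)
    stopifnot(max(abs(g - diag(ncol(component_maps)))) < 1e-8)
  }
  if (!is.null(eigenspectrum))
    stopifnot(!is.unsorted(rev(eigenspectrum)), all(eigenspectrum > 0))
  structure(
    list(
      component_maps = component_maps, subject_scores = subject_scores,
      eigenspectrum = eigenspectrum, behavior_coupling = behavior_coupling,
      gene_target_corr = gene_target_corr, flagged_frames = flagged_frames,
      seed = seed
    ),
    class = "ground_truth"
  )
}

#' Simulate one resting-state scan as parcellated BOLD plus motion traces
#'
#' One-factor model: `x_p(t) = w_p * g(t) + eps_p(t)` with `g` and `eps`
#' iid standard normal, so the population correlation between parcels p and
#' q is `w_p * w_q / sqrt((w_p^2 + 1) * (w_q^2 + 1))` and GBC is monotone
#' in `w`. Frames listed in `motion_spikes` receive a framewise
#' displacement above 0.5 mm and an intensity RMS jump in the motion
#' traces; the BOLD matrix itself is left clean, since scrubbing logic is
#' exercised on the flags.
#'
#' @param atlas a `parcel_atlas`.
#' @param n_frames number of frames (>= 50); defaults mirror a 400-frame
#'   scan at `tr = 0.7` s.
#' @param gbc_weight_map per-parcel loading `w` on the shared signal.
#' @param motion_spikes integer frame indices to contaminate.
#' @param tr repetition time in seconds.
#' @param seed integer seed.
#' @return a [parcel_ts] object.
#' @export
simulate_session <- function(atlas, n_frames = 400L, gbc_weight_map = NULL,
                             motion_spikes = integer(0), tr = 0.7,
                             seed = 1L) {
  validate_atlas(atlas)
  p <- nrow(atlas)
  stopifnot(is_count(n_frames), n_frames >= 50)
  if (is.null(gbc_weight_map)) gbc_weight_map <- rep(0.5, p)
  stopifnot(length(gbc_weight_map) == p, all(is.finite(gbc_weight_map)))
  motion_spikes <- as.integer(motion_spikes)
  stopifnot(all(motion_spikes >= 1L), all(motion_spikes <= n_frames))

  with_seed(seed, {
    g <- stats::rnorm(n_frames)
    eps <- matrix(stats::rnorm(n_frames * p), n_frames, p)
    data <- outer(g, gbc_weight_map) + eps
    colnames(data) <- atlas$parcel_id

    fd <- pmin(abs(stats::rnorm(n_frames, mean = 0.10, sd = 0.06)), 0.45)
    rms <- exp(stats::rnorm(n_frames, sd = 0.05))
    if (length(motion_spikes)) {
      fd[motion_spikes] <- stats::runif(length(motion_spikes), 0.7, 1.5)
      rms[motion_spikes] <- stats::median(rms) *
        stats::runif(length(motion_spikes), 2.5, 4)
    }
    parcel_ts(data, tr = tr, fd = fd, rms = rms)
  })
}

#' Simulate a spatially autocorrelated cortical gene-expression map
#'
#' Draws a Gaussian random field over the atlas centroids with exponential
#' spatial covariance `exp(-d / smooth_scale)`, then mixes it with the
#' standardized target map as `rho * target + sqrt(1 - rho^2) * field` so
#' the expected correlation with the target equals `target_corr`. The
#' output is standardized (mean 0, sd 1).
#'
#' @param atlas a `parcel_atlas`.
#' @param smooth_scale spatial correlation length (same units as the
#'   centroids; the synthetic atlas lives on the unit sphere).
#' @param target_map per-parcel target; must have nonzero variance.
#' @param target_corr expected correlation with the target, `|rho| < 1`.
#' @param seed integer seed.
#' @return standardized per-parcel numeric vector.
#' @export
simulate_gene_map <- function(atlas, smooth_scale = 0.5, target_map = NULL,
                              target_corr = 0, seed = 1L) {
  validate_atlas(atlas)
  p <- nrow(atlas)
  stopifnot(abs(target_corr) < 1, smooth_scale > 0)
  d <- atlas_dist(atlas)
  if (min(d[upper.tri(d)]) == 0)
    stop("degenerate geometry: duplicate centroids give a singular covariance")
  cc <- exp(-d / smooth_scale) + diag(1e-8, p)
  r <- chol(cc)
  with_seed(seed, {
    field <- standardize(as.numeric(crossprod(r, stats::rnorm(p))))
    if (target_corr == 0 || is.null(target_map)) return(field)
    target <- standardize(target_map)
    standardize(target_corr * target + sqrt(1 - target_corr^2) * field)
  })
}

#' Simulate a subjects-by-items behavioral matrix coupled to neural scores
#'
#' `B = subject_scores %*% coupling + noise`. Optionally injects missing
#' values (for imputation tests).
#'
#' @param n_subjects,n_items dimensions of the output.
#' @param subject_scores subjects x K latent score matrix.
#' @param coupling K x n_items coupling matrix.
#' @param noise_sd iid Gaussian noise sd.
#' @param missing_frac fraction of cells set to `NA` (default 0).
#' @param seed integer seed.
#' @return subjects x items numeric matrix.
#' @export
simulate_behavior <- function(n_subjects, n_items, subject_scores = NULL,
                              coupling = NULL, noise_sd = 1,
                              missing_frac = 0, seed = 1L) {
  stopifnot(is_count(n_subjects), is_count(n_items))
  if (is.null(subject_scores))
    subject_scores <- matrix(0, n_subjects, 1L)
  subject_scores <- as.matrix(subject_scores)
  stopifnot(nrow(subject_scores) == n_subjects)
  if (is.null(coupling))
    coupling <- matrix(0, ncol(subject_scores), n_items)
  coupling <- as.matrix(coupling)
  stopifnot(
    nrow(coupling) == ncol(subject_scores), ncol(coupling) == n_items,
    all(is.finite(coupling)), missing_frac >= 0, missing_frac < 1
  )
  with_seed(seed, {
    b <- subject_scores %*% coupling
    if (noise_sd > 0)
      b <- b + matrix(stats::rnorm(n_subjects * n_items, sd = noise_sd),
                      n_subjects, n_items)
    if (missing_frac > 0) {
      n_na <- floor(missing_frac * length(b))
      b[sample(length(b), n_na)] <- NA_real_
    }
    dimnames(b) <- list(paste0("sub", seq_len(n_subjects)),
                        paste0("item", seq_len(n_items)))
    b
  })
}

#' Simulate a complete pharmacological fMRI study with planted ground truth
#'
#' Convenience generator producing every input the pipeline consumes: a
#' parcel atlas, per-subject drug and placebo scans (whose GBC difference
#' carries a planted low-rank component structure), a behavioral matrix
#' coupled to the planted subject scores, and gene-expression maps with a
#' planted correlation to the first component map.
#'
#' The drug scan of subject s uses the one-factor weight map
#' `w + delta_scale * sum_k score_sk * sqrt(lambda_k) * u_k`, the placebo
#' scan uses `w`, so the drug-minus-placebo GBC map is (to first order)
#' proportional to the subject's planted component mixture.
#'
#' @param atlas a `parcel_atlas` (defaults to 718 parcels, 12 networks).
#' @param n_subjects number of subjects.
#' @param k number of planted neural components.
#' @param eigenspectrum planted component eigenvalues (relative weights of
#'   the inter-individual axes).
#' @param delta_scale scaling of the drug-induced weight-map perturbation.
#' @param n_frames frames per scan.
#' @param n_items behavioral items.
#' @param behavior_coupling K x n_items coupling of behavior to the planted
#'   scores (default couples the first two components).
#' @param behavior_noise_sd behavioral noise sd.
#' @param gene_target_corr named vector of planted correlations between
#'   gene maps and the first component map (default `c(SST = 0.47,
#'   PVALB = -0.22)`, the effect scale reported for interneuron marker
#'   genes in pharmacological GBC work).
#' @param smooth_scale spatial correlation length of the gene fields.
#' @param seed integer seed.
#' @return list with `atlas`, `sessions` (per subject: `drug`, `placebo`
#'   [parcel_ts]), `behavior` (drug and placebo matrices), `gene_maps`,
#'   `truth`.
#' @export
simulate_study <- function(atlas = make_atlas(718L, 12L, seed = 1L),
                           n_subjects = 40L, k = 5L,
                           eigenspectrum = c(60, 45, 30, 25, 20),
                           delta_scale = 0.2, n_frames = 400L,
                           n_items = 31L, behavior_coupling = NULL,
                           behavior_noise_sd = 1,
                           gene_target_corr = c(SST = 0.47, PVALB = -0.22),
                           smooth_scale = 0.5, seed = 1L) {
  validate_atlas(atlas)
  p <- nrow(atlas)
  base <- simulate_delta_gbc(atlas, n_subjects, k, eigenspectrum,
                             noise_sd = 0, seed = seed)
  u <- base$truth$component_maps
  scores <- base$truth$subject_scores

  if (is.null(behavior_coupling)) {
    behavior_coupling <- matrix(0, k, n_items)
    behavior_coupling[1L, seq_len(ceiling(n_items / 2))] <- 1.2
    behavior_coupling[min(2L, k), (ceiling(n_items / 2) + 1L):n_items] <- 0.9
  }

  w0 <- rep(0.5, p)
  sessions <- lapply(seq_len(n_subjects), function(s) {
    pert <- as.numeric(u %*% (sqrt(eigenspectrum) * scores[s, ]))
    list(
      drug = simulate_session(atlas, n_frames, w0 + delta_scale * pert,
                              seed = seed + 1000L + s),
      placebo = simulate_session(atlas, n_frames, w0,
                                 seed = seed + 2000L + s)
    )
  })
  names(sessions) <- rownames(base$maps)

  behavior <- list(
    drug = simulate_behavior(n_subjects, n_items, scores, behavior_coupling,
                             noise_sd = behavior_noise_sd,
                             seed = seed + 3000L),
    placebo = simulate_behavior(n_subjects, n_items,
                                matrix(0, n_subjects, k), behavior_coupling,
                                noise_sd = behavior_noise_sd,
                                seed = seed + 4000L)
  )

  gene_maps <- lapply(seq_along(gene_target_corr), function(i) {
    simulate_gene_map(atlas, smooth_scale, target_map = u[, 1L],
                      target_corr = gene_target_corr[[i]],
                      seed = seed + 5000L + i)
  })
  names(gene_maps) <- names(gene_target_corr)

  truth <- ground_truth(
    component_maps = u, subject_scores = scores,
    eigenspectrum = eigenspectrum, behavior_coupling = behavior_coupling,
    gene_target_corr = gene_target_corr, seed = seed
  )
  list(atlas = atlas, sessions = sessions, behavior = behavior,
       gene_maps = gene_maps, truth = truth)
}
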
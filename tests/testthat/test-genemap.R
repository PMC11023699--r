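test_that("empirical variogram matches brute-force pair enumeration", {
  atlas <- small_atlas(8, 2, seed = 4)
  d <- atlas_dist(atlas)
  set.seed(71)
  map <- stats::rnorm(8)
  v <- suppressWarnings(empirical_variogram(map, d, n_bins = 4))
  bf <- brute_force_variogram(map, d, n_bins = 4)
  expect_equal(v$gamma, bf$gamma, tolerance = 1e-12)
  expect_equal(v$centers, bf$centers, tolerance = 1e-12)

  # constant map: flat zero variogram
  v0 <- suppressWarnings(empirical_variogram(rep(2, 8), d, n_bins = 4))
  expect_true(all(v0$gamma == 0))
})

test_that("a coordinate map yields a monotone-trending variogram", {
  atlas <- small_atlas(100, 4)
  d <- atlas_dist(atlas)
  v <- empirical_variogram(atlas$x, d, n_bins = 15)
  expect_gt(stats::cor(v$centers, v$gamma, method = "spearman"), 0.8)
})

test_that("surrogates beat the permutation baseline on smooth fields", {
  atlas <- small_atlas(200, 12)
  d <- atlas_dist(atlas)
  ratios <- vapply(1:5, function(s) {
    target <- simulate_gene_map(atlas, 1.5, seed = 100 + s)
    ens <- generate_surrogates(target, d, m = 200, seed = s,
                               hemi = atlas$hemisphere)
    stats::median(ens$variogram_sse / ens$sse_permutation)
  }, numeric(1))
  # core fidelity property: variogram matched far better than permutation
  expect_lt(stats::median(ratios), 0.5)
  # by construction, no surrogate is ever worse than its own permutation
  target <- simulate_gene_map(atlas, 0.5, seed = 9)
  ens <- generate_surrogates(target, d, m = 100, seed = 3,
                             hemi = atlas$hemisphere)
  expect_true(all(ens$variogram_sse <= ens$sse_permutation + 1e-12))
})

test_that("surrogate ensembles are reproducible and near-neutral on iid maps", {
  atlas <- small_atlas(100, 4)
  d <- atlas_dist(atlas)
  target <- deltagbc:::with_seed(5, stats::rnorm(100))
  e1 <- generate_surrogates(target, d, m = 50, seed = 11)
  e2 <- generate_surrogates(target, d, m = 50, seed = 11)
  expect_identical(e1$maps, e2$maps)
  # no autocorrelation to match: surrogates are ~ plain permutations
  expect_gt(stats::median(e1$variogram_sse / e1$sse_permutation), 0.7)
})

test_that("single-parcel hemispheres fall back to whole-map generation", {
  atlas <- small_atlas(30, 2, seed = 2)
  d <- atlas_dist(atlas)
  hemi <- c("L", rep("R", 29))
  expect_warning(
    generate_surrogates(stats::rnorm(30), d, m = 5, seed = 1, hemi = hemi),
    "fewer than 2"
  )
})

test_that("surrogate correlation test has the right floor and invariances", {
  atlas <- small_atlas(100, 4)
  d <- atlas_dist(atlas)
  target <- simulate_gene_map(atlas, 0.5, seed = 21)
  ens <- generate_surrogates(target, d, m = 199, seed = 2,
                             hemi = atlas$hemisphere)
  self <- surrogate_correlation_test(target, target, ens)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)

  gene <- simulate_gene_map(atlas, 0.5, seed = 22)
  base <- surrogate_correlation_test(target, gene, ens)
  shifted <- surrogate_correlation_test(target, 3 * gene + 7, ens)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  expect_identical(shifted$p, base$p)
  # positive-affine transform of the target reproduces the same p exactly
  ens_aff <- generate_surrogates(2 * target + 1, d, m = 199, seed = 2,
                                 hemi = atlas$hemisphere)
  aff <- surrogate_correlation_test(2 * target + 1, gene, ens_aff)
  expect_equal(aff$r, base$r, tolerance = 1e-10)
  expect_identical(aff$p, base$p)
})

test_that("p-values from independent ensembles agree within Monte-Carlo error", {
  atlas <- small_atlas(100, 4)
  d <- atlas_dist(atlas)
  target <- simulate_gene_map(atlas, 0.5, seed = 31)
  gene <- 0.4 * target + 0.9 * simulate_gene_map(atlas, 0.5, seed = 32)
  m <- 500
  p1 <- surrogate_correlation_test(
    target, gene, generate_surrogates(target, d, m, seed = 1))$p
  p2 <- surrogate_correlation_test(
    target, gene, generate_surrogates(target, d, m, seed = 2))$p
  pbar <- (p1 + p2) / 2
  expect_lt(abs(p1 - p2), 4 * sqrt(pbar * (1 - pbar) / m) + 1e-9)
})

test_that("gene screening applies the differential-stability band", {
  genes <- data.frame(
    gene = c("a", "b", "c", "d"),
    differential_stability = c(0.05, -0.5, 0.11, 0.1)
  )
  kept <- screen_genes(genes)
  expect_setequal(kept$gene, c("b", "c"))
  expect_setequal(attr(kept, "excluded"), c("a", "d"))
})

test_that("BH correction matches the hand computation", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(fdr_correct(rep(0.2, 4)), rep(0.2, 4))
  p <- c(0.001, 0.04, 0.3, 0.7, 1)
  expect_true(all(fdr_correct(p) >= p))
  expect_error(fdr_correct(c(0, 0.5)))
})

test_that("subject gene profiles label planted sign patterns", {
  atlas <- small_atlas(100, 4)
  u <- simulate_delta_gbc(atlas, 10, 1, 4, noise_sd = 0,
                          seed = 3)$truth$component_maps[, 1]
  gene_a <- simulate_gene_map(atlas, 0.5, u, 0.5, seed = 41)
  gene_b <- simulate_gene_map(atlas, 0.5, u, -0.5, seed = 42)
  # 60% of subjects load +u, the rest -u
  signs <- rep(c(1, -1), c(12, 8))
  maps <- outer(signs, u) +
    deltagbc:::with_seed(43, matrix(stats::rnorm(20 * 100, sd = 0.02), 20, 100))
  prof <- subject_gene_profile(maps, list(A = gene_a, B = gene_b),
                               m_per_subject = 0)
  expect_equal(sum(attr(prof, "pattern_counts")), 20)
  expect_gte(mean(prof$pattern[1:12] == "+-"), 0.8)

  # a subject map equal to a gene map pins its correlation at 1
  maps2 <- rbind(gene_a, maps[1:4, ])
  prof2 <- subject_gene_profile(maps2, list(A = gene_a, B = gene_b),
                                m_per_subject = 0)
  expect_equal(prof2$r_A[1], 1, tolerance = 1e-12)
  expect_equal(prof2$r_B[1], stats::cor(gene_a, gene_b), tolerance = 1e-12)
})

test_that("subject profiles carry surrogate p-values when requested", {
  atlas <- small_atlas(60, 4)
  d <- atlas_dist(atlas)
  u <- simulate_delta_gbc(atlas, 5, 1, 4, noise_sd = 0,
                          seed = 3)$truth$component_maps[, 1]
  maps <- outer(c(1, -1, 1), u)
  maps <- maps + deltagbc:::with_seed(7, matrix(stats::rnorm(180, sd = 0.05), 3, 60))
  gene <- simulate_gene_map(atlas, 0.5, u, 0.9, seed = 44)
  other <- simulate_gene_map(atlas, 0.5, seed = 45)
  prof <- subject_gene_profile(maps, list(g = gene, o = other), dist = d,
                               m_per_subject = 99, seed = 5)
  expect_true(all(prof$p_g >= 1 / 100 & prof$p_g <= 1))
  expect_lt(prof$p_g[1], 0.2)  # strongly matched subject
})
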
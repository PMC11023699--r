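test_that("mass-univariate slopes match the per-parcel OLS oracle", {
  set.seed(91)
  maps <- matrix(stats::rnorm(20 * 15), 20, 15)
  score <- stats::rnorm(20)
  nb <- mass_univariate_map(maps, score)
  z <- (score - mean(score)) / stats::sd(score)
  oracle <- vapply(1:15, function(p)
    unname(stats::coef(stats::lm(maps[, p] ~ z))[2]), numeric(1))
  expect_equal(nb$coef_raw, oracle, tolerance = 1e-10)
  expect_lt(abs(mean(nb$coef_z)), 1e-12)
  expect_equal(stats::sd(nb$coef_z), 1, tolerance = 1e-12)
  expect_error(mass_univariate_map(maps, rep(1, 20)), "zero variance")
})

test_that("null slopes shrink with the square root of the sample size", {
  med_max <- vapply(c(20L, 80L, 320L), function(s) {
    stats::median(vapply(1:20, function(rep) {
      maps <- deltagbc:::with_seed(1000 * s + rep,
                                   matrix(stats::rnorm(s * 30), s, 30))
      score <- deltagbc:::with_seed(2000 * s + rep, stats::rnorm(s))
      max(abs(mass_univariate_map(maps, score)$coef_raw))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_max) < 0))
  # 16x the sample should shrink the max statistic by roughly 4
  expect_equal(med_max[1] / med_max[3], 4, tolerance = 0.35)
})

test_that("a planted coefficient map is localized correctly", {
  hits <- vapply(1:20, function(s) {
    v <- deltagbc:::with_seed(s, stats::rnorm(40))
    score <- deltagbc:::with_seed(100 + s, stats::rnorm(60))
    maps <- outer(score, v) +
      deltagbc:::with_seed(200 + s, matrix(stats::rnorm(60 * 40), 60, 40))
    nb <- mass_univariate_map(maps, score)
    which.max(abs(nb$coef_z)) %in% order(abs(v), decreasing = TRUE)[1:5]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("max-stat corrected p-values dominate parametric ones", {
  set.seed(92)
  maps <- matrix(stats::rnorm(25 * 30), 25, 30)
  score <- stats::rnorm(25)
  res <- permutation_correct(maps, score, n_perm = 300, seed = 1)
  r <- as.numeric(stats::cor(score, maps))
  t_par <- r * sqrt(23) / sqrt(1 - r^2)
  p_par <- 2 * stats::pt(-abs(t_par), 23)
  expect_true(all(res$p_corrected >= p_par - 1e-12))
  expect_true(all(res$p_corrected >= 1 / 301 & res$p_corrected <= 1))
  expect_identical(res$p_corrected,
                   permutation_correct(maps, score, n_perm = 300,
                                       seed = 1)$p_corrected)
})

test_that("TFCE enhances a planted contiguous cluster", {
  atlas <- small_atlas(40, 4)
  adj <- knn_adjacency(atlas, k = 4)
  d <- atlas_dist(atlas)
  # cluster = a parcel and its spatial neighbours
  cl <- order(d[1, ])[1:6]
  v <- numeric(40)
  v[cl] <- 1
  score <- deltagbc:::with_seed(93, stats::rnorm(35))
  maps <- outer(score, v) +
    deltagbc:::with_seed(94, matrix(stats::rnorm(35 * 40, sd = 0.6), 35, 40))
  res <- permutation_correct(maps, score, n_perm = 200, method = "tfce",
                             adjacency = adj, seed = 2)
  expect_lt(min(res$p_corrected[cl]), 0.05)
  expect_error(permutation_correct(maps, score, method = "tfce"),
               "adjacency")
})

test_that("disconnected adjacency triggers a warning under TFCE", {
  maps <- deltagbc:::with_seed(95, matrix(stats::rnorm(20 * 6), 20, 6))
  score <- deltagbc:::with_seed(96, stats::rnorm(20))
  adj <- matrix(FALSE, 6, 6)
  adj[1, 2] <- adj[2, 1] <- TRUE
  adj[3, 4] <- adj[4, 3] <- TRUE  # nodes 5-6 isolated
  expect_warning(
    permutation_correct(maps, score, n_perm = 100, method = "tfce",
                        adjacency = adj, seed = 1),
    "disconnected"
  )
})

test_that("subject projections are z-scored and flag degenerate maps", {
  set.seed(97)
  ref <- stats::rnorm(50)
  maps <- rbind(ref, matrix(stats::rnorm(9 * 50), 9, 50))
  proj <- subject_projection(maps, ref)
  expect_equal(proj$r[1], 1, tolerance = 1e-12)
  expect_equal(which.max(proj$r), 1L)
  expect_lt(abs(mean(proj$z)), 1e-12)
  expect_equal(stats::sd(proj$z), 1, tolerance = 1e-12)

  maps_bad <- rbind(maps, rep(3, 50))
  proj_bad <- subject_projection(maps_bad, ref)
  expect_true(proj_bad$flagged[11])
  expect_true(is.na(proj_bad$z[11]))
  expect_equal(mean(proj_bad$z, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("projection of a linear combination equals the combined correlation", {
  set.seed(98)
  maps <- matrix(stats::rnorm(12 * 30), 12, 30)
  ref <- stats::rnorm(30)
  w <- stats::rnorm(12)
  direct <- stats::cor(as.numeric(crossprod(maps, w)), ref)
  # expansion through centered covariances
  centered <- scale(t(maps), scale = FALSE)
  ref_c <- ref - mean(ref)
  num <- sum(w * crossprod(centered, ref_c))
  comb <- as.numeric(centered %*% w)
  indirect <- num / (sqrt(sum(comb^2)) * sqrt(sum(ref_c^2)))
  expect_equal(direct, indirect, tolerance = 1e-10)
})

test_that("gene coupling correlation recovers a planted relationship", {
  atlas <- small_atlas(80, 4)
  u <- simulate_delta_gbc(atlas, 5, 1, 4, noise_sd = 0,
                          seed = 3)$truth$component_maps[, 1]
  gene_a <- simulate_gene_map(atlas, 0.5, u, 0.6, seed = 51)
  gene_b <- simulate_gene_map(atlas, 0.5, u, -0.6, seed = 52)
  score <- deltagbc:::with_seed(53, stats::rnorm(25))
  maps <- outer(score, u) +
    deltagbc:::with_seed(54, matrix(stats::rnorm(25 * 80, sd = 0.3), 25, 80))
  prof <- subject_gene_profile(maps, list(A = gene_a, B = gene_b),
                               m_per_subject = 0)
  proj <- subject_projection(maps, u)
  res <- gene_coupling_correlation(prof, proj, n_perm = 200, seed = 1)
  expect_false(res$degenerate)
  expect_gt(res$r, 0.5)
  expect_lt(res$p, 0.01)
  expect_true(res$p_perm >= 1 / 201 && res$p_perm <= 1)

  # constant difference: degenerate contract
  prof0 <- data.frame(r_A = rep(0.3, 25), r_B = rep(0.1, 25))
  expect_true(gene_coupling_correlation(prof0, proj)$degenerate)
})
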
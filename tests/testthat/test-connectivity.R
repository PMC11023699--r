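test_that("frame flagging applies thresholds and the neighbour rule", {
  # FD spike at frame 2 drags frames 1 and 3 along
  expect_identical(which(compute_frame_flags(c(0.1, 0.6, 0.2, 0.1), rep(1, 4))),
                   1:3)
  # benign traces stay clean
  expect_false(any(compute_frame_flags(rep(0.1, 10), rep(1, 10))))
  # RMS spike at the last frame (median 1, 10 > 1.6) flags it plus frame 3
  expect_identical(which(compute_frame_flags(rep(0.1, 4), c(1, 1, 1, 10))),
                   3:4)
  expect_error(compute_frame_flags(numeric(0), numeric(0)), "empty")
})

test_that("scrubbing removes flagged frames or excludes the subject", {
  mk <- function(flags) {
    n <- length(flags)
    parcel_ts(matrix(seq_len(n * 3), n, 3), tr = 1, fd = numeric(n),
              rms = rep(1, n), flags = flags)
  }
  # 6 of 10 flagged: more than half -> exclusion marker
  excl <- scrub(mk(rep(c(TRUE, FALSE), c(6, 4))))
  expect_true(is_excluded(excl))
  expect_equal(excl$flagged_frac, 0.6)
  # 2 of 10 flagged: 8 frames survive, order preserved
  ts <- mk(c(TRUE, TRUE, rep(FALSE, 8)))
  out <- scrub(ts, min_frames = 5)
  expect_equal(nrow(out$data), 8)
  expect_identical(out$data, ts$data[3:10, ])
  # nothing flagged: identical data
  clean <- scrub(mk(rep(FALSE, 40)))
  expect_identical(clean$data, mk(rep(FALSE, 40))$data)
  # too few survivors is an error, not a silent result
  expect_error(scrub(mk(c(TRUE, rep(FALSE, 9)))), "too few frames")
})

test_that("high-pass regression removes slow drift and keeps fast signal", {
  n <- 400
  tr <- 0.7
  tt <- seq_len(n) * tr
  slow <- sin(2 * pi * 0.002 * tt)   # cutoff / 4
  fast <- sin(2 * pi * 0.08 * tt)    # 10x cutoff
  ts <- parcel_ts(cbind(slow, fast, 2), tr = tr)
  hp <- highpass(ts)
  expect_lt(stats::var(hp$data[, 1]) / stats::var(slow), 0.1)
  expect_gt(stats::var(hp$data[, 2]) / stats::var(fast), 0.9)
  expect_lt(max(abs(hp$data[, 3])), 1e-12)       # exact DC removal
  expect_lt(max(abs(colMeans(hp$data))), 1e-12)
  expect_error(highpass(parcel_ts(matrix(0, 60, 2), tr = 1), cutoff = 0.6),
               "Nyquist")
})

test_that("nuisance regression orthogonalizes against the full design", {
  set.seed(21)
  n <- 120
  nuis <- matrix(stats::rnorm(n * 2), n, 2)
  data <- cbind(nuis[, 1], matrix(stats::rnorm(n * 4), n, 4))
  ts <- parcel_ts(data, tr = 1)
  out <- nuisance_regress(ts, nuis, gsr = FALSE)
  # a column equal to a nuisance regressor is annihilated
  expect_lt(max(abs(out$data[, 1])), 1e-8)
  # residuals orthogonal to every regressor and its derivative
  design <- cbind(nuis, rbind(0, diff(nuis)))
  cors <- abs(stats::cor(out$data[, -1], design))
  expect_lt(max(cors), 1e-8)
})

test_that("global signal regression zeroes the mean across parcels", {
  set.seed(22)
  ts <- parcel_ts(matrix(stats::rnorm(100 * 8), 100, 8) +
                    stats::rnorm(100), tr = 1)
  out <- nuisance_regress(ts, gsr = TRUE)
  expect_lt(max(abs(rowMeans(out$data))), 1e-10)
})

test_that("collinear design columns are dropped with a warning", {
  set.seed(23)
  nuis <- matrix(stats::rnorm(80), 80, 1)
  nuis <- cbind(nuis, nuis)  # duplicated column
  ts <- parcel_ts(matrix(stats::rnorm(80 * 3), 80, 3), tr = 1)
  expect_warning(nuisance_regress(ts, nuis, add_derivatives = FALSE,
                                  gsr = FALSE), "collinear")
})

test_that("FC matrix clips degenerate pairs and matches atanh", {
  set.seed(31)
  base <- stats::rnorm(60)
  # construct an exact r = 0.5 pair
  resid <- stats::residuals(stats::lm(stats::rnorm(60) ~ base))
  y <- 0.5 * standardize(base) + sqrt(0.75) * standardize(resid)
  ts <- parcel_ts(cbind(base, y, base, stats::rnorm(60)), tr = 1)
  fc <- fc_matrix(ts)
  expect_equal(fc$z[1, 2], atanh(0.5), tolerance = 1e-4)
  expect_equal(fc$z[1, 3], atanh(1 - 1e-7))  # identical columns, finite
  expect_true(all(is.finite(fc$z)))
  expect_equal(unname(diag(fc$z)), rep(0, 4))

  long <- parcel_ts(matrix(stats::rnorm(5000 * 3), 5000, 3), tr = 1)
  z_long <- fc_matrix(long)$z
  expect_lt(max(abs(z_long[upper.tri(z_long)])), 0.05)

  bad <- parcel_ts(cbind(stats::rnorm(40), rep(1, 40)), tr = 1)
  expect_error(fc_matrix(bad), "zero-variance parcel")
  expect_error(fc_matrix(parcel_ts(matrix(stats::rnorm(29 * 2), 29, 2),
                                   tr = 1)), "30 frames")
})

test_that("GBC equals the row mean over the off-diagonal", {
  z <- matrix(0.5, 3, 3)
  diag(z) <- 0
  fc <- structure(list(z = z, n_frames_used = 100), class = "fc_matrix")
  expect_equal(gbc(fc)$values, rep(0.5, 3))

  z2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  fc2 <- structure(list(z = z2, n_frames_used = 100), class = "fc_matrix")
  expect_equal(gbc(fc2)$values, c(0.3, 0.3))

  set.seed(41)
  m <- matrix(stats::rnorm(36), 6, 6)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  fc3 <- structure(list(z = m, n_frames_used = 100), class = "fc_matrix")
  oracle <- vapply(1:6, function(x) mean(m[x, -x]), numeric(1))
  expect_equal(gbc(fc3)$values, oracle, tolerance = 1e-15)
})

test_that("delta GBC is an elementwise difference with atlas checks", {
  g1 <- gbc(fc_matrix(parcel_ts(matrix(stats::rnorm(200), 50, 4), tr = 1)))
  g2 <- gbc(fc_matrix(parcel_ts(matrix(stats::rnorm(200), 50, 4), tr = 1)))
  expect_equal(delta_gbc(g1, g1)$values, rep(0, 4))
  g3 <- g1
  g3$values <- g1$values + 2
  expect_equal(delta_gbc(g3, g1)$values, rep(2, 4))
  expect_equal(delta_gbc(g1, g2)$values, g1$values - g2$values)
  g_small <- gbc(fc_matrix(parcel_ts(matrix(stats::rnorm(150), 50, 3),
                                     tr = 1)))
  expect_error(delta_gbc(g1, g_small), "mismatch")
})

test_that("pipeline GBC equals the brute-force single-pass oracle", {
  atlas <- small_atlas(40, 4)
  ts <- simulate_session(atlas, 120, stats::runif(40, 0.2, 1), seed = 8)
  expect_equal(gbc(fc_matrix(ts))$values, brute_force_gbc(ts$data),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("scrub-then-FC equals FC on the manually subsetted frames", {
  atlas <- small_atlas(30, 4)
  ts <- simulate_session(atlas, 80, rep(0.5, 30), seed = 12)
  flags <- rep(FALSE, 80)
  flags[c(3, 4, 50)] <- TRUE
  ts$flags <- flags
  via_scrub <- fc_matrix(scrub(ts))
  manual <- fc_matrix(parcel_ts(ts$data[!flags, ], tr = ts$tr))
  expect_identical(via_scrub$z, manual$z)
})

test_that("exclusion propagates through preprocess_session", {
  atlas <- small_atlas(30, 4)
  ts <- simulate_session(atlas, 100, rep(0.5, 30),
                         motion_spikes = seq(2, 98, by = 2), seed = 13)
  ts$flags <- compute_frame_flags(ts$fd, ts$rms)
  expect_true(is_excluded(preprocess_session(ts)))
})
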
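# Shared fixtures, built in code at test time.

# Small atlases reused across files (cached per session).
small_atlas <- local({
  cache <- list()
  function(n_parcels = 40L, n_networks = 4L, seed = 1L) {
    key <- paste(n_parcels, n_networks, seed, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <<- make_atlas(n_parcels, n_networks, seed = seed)
    cache[[key]]
  }
})

# Independent brute-force GBC: per-parcel loop over all other parcels,
# Pearson -> clipped atanh -> mean. Deliberately single-pass and slow.
brute_force_gbc <- function(data) {
  p <- ncol(data)
  clip <- 1 - 1e-7
  vapply(seq_len(p), function(x) {
    acc <- 0
    for (y in seq_len(p)) {
      if (y == x) next
      r <- stats::cor(data[, x], data[, y])
      r <- max(min(r, clip), -clip)
      acc <- acc + atanh(r)
    }
    acc / (p - 1)
  }, numeric(1))
}

# Largest principal angle (degrees) between the column spaces of U and V.
principal_angle_deg <- function(U, V) {
  qu <- qr.Q(qr(U))
  qv <- qr.Q(qr(V))
  sv <- svd(crossprod(qu, qv))$d
  acos(min(pmax(pmin(sv, 1), -1))) * 180 / pi
}

# Brute-force binned variogram by explicit pair enumeration.
brute_force_variogram <- function(map, dist, n_bins) {
  p <- length(map)
  pairs <- t(utils::combn(p, 2))
  d <- dist[pairs]
  sq <- 0.5 * (map[pairs[, 1]] - map[pairs[, 2]])^2
  breaks <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(d, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  list(centers = as.numeric(tapply(d, bin, mean)),
       gamma = as.numeric(tapply(sq, bin, mean)))
}
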
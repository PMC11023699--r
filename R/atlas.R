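#' Construct a synthetic whole-brain parcel atlas
#'
#' Builds a parcel table emulating a functional network parcellation:
#' parcels carry a hemisphere, one of `n_networks` network labels (names
#' follow the CAB-NP convention: default mode, frontoparietal, ... down to
#' primary visual), a coarse class (`association` or `sensory`, balanced by
#' design so that network-contrast tests have equal groups), and a 3-D
#' centroid. Centroids are placed on the unit sphere with a Fibonacci
#' lattice, which is deterministic and keeps pairwise distances
#' non-degenerate -- a requirement for the variogram-matched surrogate
#' machinery. Hemispheres are assigned by the sign of the first centroid
#' axis.
#'
#' @param n_parcels number of parcels (at least `2 * n_networks`).
#' @param n_networks even number of network labels; half are tagged
#'   `association`, half `sensory`.
#' @param seed integer seed controlling the (random) assignment of parcels
#'   to networks.
#' @return a `parcel_atlas` data frame with columns `parcel_id`,
#'   `hemisphere`, `network`, `klass`, `x`, `y`, `z`.
#' @examples
#' atlas <- make_atlas(24, n_networks = 4, seed = 1)
#' table(atlas$network, atlas$klass)
#' @export
make_atlas <- function(n_parcels, n_networks = 12L, seed = 1L) {
  stopifnot(is_count(n_parcels), is_count(n_networks))
  if (n_networks %% 2L != 0L)
    stop("n_networks must be even (half association, half sensory)")
  if (n_parcels < 2L * n_networks)
    stop("n_parcels must be at least 2 * n_networks")

  # Fibonacci lattice on the unit sphere
  i <- seq_len(n_parcels) - 0.5
  phi <- acos(1 - 2 * i / n_parcels)
  theta <- pi * (1 + sqrt(5)) * i
  cx <- sin(phi) * cos(theta)
  cy <- sin(phi) * sin(theta)
  cz <- cos(phi)

  hemisphere <- ifelse(cx < 0, "L", "R")
  networks <- network_labels(n_networks)
  net_idx <- rep(seq_len(n_networks), length.out = n_parcels)
  net_idx <- with_seed(seed, sample(net_idx))

  atlas <- data.frame(
    parcel_id = seq_len(n_parcels),
    hemisphere = hemisphere,
    network = factor(networks$name[net_idx], levels = networks$name),
    klass = factor(networks$klass[net_idx], levels = c("association", "sensory")),
    x = cx, y = cy, z = cz,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("parcel_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

# Network label pool. The first twelve names mirror the CAB-NP networks;
# larger atlases fall back to generated labels.
network_labels <- function(n_networks) {
  assoc <- c("DMN", "FPN", "LAN", "OAN", "VMM", "PMM")
  sens <- c("VIS", "VIS2", "SOM", "AUD", "CON", "DAN")
  half <- n_networks %/% 2L
  if (half > length(assoc)) {
    assoc <- c(assoc, paste0("ASSOC", seq_len(half - length(assoc))))
    sens <- c(sens, paste0("SENS", seq_len(half - length(sens))))
  }
  data.frame(
    name = c(assoc[seq_len(half)], sens[seq_len(half)]),
    klass = rep(c("association", "sensory"), each = half),
    stringsAsFactors = FALSE
  )
}

validate_atlas <- function(atlas) {
  stopifnot(
    inherits(atlas, "data.frame"),
    all(c("parcel_id", "hemisphere", "network", "klass", "x", "y", "z") %in%
          names(atlas))
  )
  if (!identical(as.integer(atlas$parcel_id), seq_len(nrow(atlas))))
    stop("parcel_ids must be unique and contiguous from 1")
  if (anyNA(atlas$network) || anyNA(atlas$klass))
    stop("every parcel needs a network and a klass")
  if (length(unique(atlas$hemisphere)) < 2L)
    stop("both hemispheres must be non-empty")
  if (!all(is.finite(as.matrix(atlas[, c("x", "y", "z")]))))
    stop("centroids must be finite")
  invisible(atlas)
}

atlas_centroids <- function(atlas) {
  as.matrix(atlas[, c("x", "y", "z")])
}

#' Pairwise centroid distance matrix of an atlas
#'
#' @param atlas a `parcel_atlas`.
#' @return a symmetric parcels-by-parcels Euclidean distance matrix.
#' @export
atlas_dist <- function(atlas) {
  validate_atlas(atlas)
  as.matrix(stats::dist(atlas_centroids(atlas)))
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat(sprintf(
    "parcel_atlas: %d parcels, %d networks (%d association / %d sensory parcels)\n",
    nrow(x), nlevels(x$network),
    sum(x$klass == "association"), sum(x$klass == "sensory")
  ))
  NextMethod()
}
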
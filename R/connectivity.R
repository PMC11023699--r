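# From parcellated BOLD to denoised functional connectivity and GBC.

#' Parcellated BOLD time series with motion traces
#'
#' @param data frames x parcels numeric matrix.
#' @param tr repetition time, seconds.
#' @param fd per-frame framewise displacement, mm.
#' @param rms per-frame normalized intensity RMS (unitless).
#' @param flags optional logical per-frame flag vector (computed by
#'   [compute_frame_flags] if omitted there).
#' @return a `parcel_ts` object.
#' @export
parcel_ts <- function(data, tr, fd = NULL, rms = NULL, flags = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  stopifnot(is.numeric(tr), tr > 0, n >= 1L)
  if (is.null(fd)) fd <- numeric(n)
  if (is.null(rms)) rms <- rep(1, n)
  stopifnot(length(fd) == n, length(rms) == n)
  if (!is.null(flags)) stopifnot(is.logical(flags), length(flags) == n)
  structure(
    list(data = data, tr = tr, fd = as.numeric(fd), rms = as.numeric(rms),
         flags = flags),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("parcel_ts: %d frames x %d parcels, tr = %.3g s", nrow(x$data),
              ncol(x$data), x$tr))
  if (!is.null(x$flags)) cat(sprintf(", %d flagged frames", sum(x$flags)))
  cat("\n")
  invisible(x)
}

n_frames <- function(ts) nrow(ts$data)

#' Flag motion-contaminated frames
#'
#' A frame is flagged when framewise displacement exceeds `fd_thresh` (mm)
#' or the normalized intensity RMS exceeds `rms_mult` times the median RMS
#' of the scan; the frame immediately preceding and immediately following
#' any flagged frame is flagged as well.
#'
#' @param fd per-frame framewise displacement, mm.
#' @param rms per-frame normalized intensity RMS.
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @param rms_mult multiple of the median RMS (default 1.6).
#' @return logical vector, `TRUE` for discarded frames.
#' @examples
#' compute_frame_flags(c(0.1, 0.6, 0.2, 0.1), rep(1, 4))
#' @export
compute_frame_flags <- function(fd, rms, fd_thresh = 0.5, rms_mult = 1.6) {
  fd <- as.numeric(fd)
  rms <- as.numeric(rms)
  if (length(fd) == 0L) stop("empty motion traces")
  stopifnot(length(fd) == length(rms), all(fd >= 0), all(rms >= 0))
  core <- fd > fd_thresh | rms > rms_mult * stats::median(rms)
  # dilate by one frame on each side
  n <- length(core)
  core | c(core[-1L], FALSE) | c(FALSE, core[-n])
}

#' Remove flagged frames, or signal subject exclusion
#'
#' Frames flagged in `ts$flags` (computed from the motion traces if absent)
#' are dropped from the data and traces. If more than `max_flag_frac` of
#' the frames are flagged the subject is excluded: a `subject_exclusion`
#' marker is returned instead of data. Fewer than `min_frames` surviving
#' frames is an error, since correlation estimates below that are unusable.
#'
#' @param ts a [parcel_ts].
#' @param max_flag_frac maximum tolerated flagged fraction (default 0.5).
#' @param min_frames minimum surviving frames (default 30).
#' @return a scrubbed `parcel_ts`, or a `subject_exclusion` object.
#' @export
scrub <- function(ts, max_flag_frac = 0.5, min_frames = 30L) {
  stopifnot(inherits(ts, "parcel_ts"))
  flags <- ts$flags
  if (is.null(flags)) flags <- compute_frame_flags(ts$fd, ts$rms)
  frac <- mean(flags)
  if (frac > max_flag_frac) {
    return(structure(
      list(flagged_frac = frac, n_flagged = sum(flags),
           n_frames = length(flags)),
      class = "subject_exclusion"
    ))
  }
  keep <- !flags
  if (sum(keep) < min_frames)
    stop(sprintf("too few frames: %d survive scrubbing (< %d)", sum(keep),
                 min_frames))
  parcel_ts(ts$data[keep, , drop = FALSE], tr = ts$tr, fd = ts$fd[keep],
            rms = ts$rms[keep], flags = rep(FALSE, sum(keep)))
}

#' @export
print.subject_exclusion <- function(x, ...) {
  cat(sprintf("subject excluded: %d/%d frames flagged (%.0f%%)\n",
              x$n_flagged, x$n_frames, 100 * x$flagged_frac))
  invisible(x)
}

#' Is this scrub result a subject exclusion?
#' @param x a [scrub] result.
#' @export
is_excluded <- function(x) inherits(x, "subject_exclusion")

# Discrete-cosine basis whose components have frequency below `cutoff`.
# DCT component j over N frames sampled at tr has frequency j / (2 N tr).
dct_lowfreq_basis <- function(n, tr, cutoff) {
  j_max <- ceiling(cutoff * 2 * n * tr) - 1L  # j with freq < cutoff
  if (j_max < 1L) return(NULL)
  t_idx <- seq_len(n) - 0.5
  vapply(seq_len(j_max), function(j) cos(pi * j * t_idx / n), numeric(n))
}

#' High-pass filter via discrete-cosine basis regression
#'
#' Removes the mean and every DCT regressor with frequency below `cutoff`
#' from each parcel's time series. Regression filtering gives exact DC
#' removal, no ringing, and composes with nuisance regression.
#'
#' @param ts a [parcel_ts].
#' @param cutoff high-pass cutoff in Hz (default 0.008).
#' @return filtered `parcel_ts` (column means ~ 0).
#' @export
highpass <- function(ts, cutoff = 0.008) {
  stopifnot(inherits(ts, "parcel_ts"))
  n <- n_frames(ts)
  stopifnot(n >= 50)
  nyquist <- 1 / (2 * ts$tr)
  if (cutoff >= nyquist)
    stop(sprintf("cutoff %.4g Hz is at or above Nyquist (%.4g Hz)", cutoff,
                 nyquist))
  design <- cbind(1, dct_lowfreq_basis(n, ts$tr, cutoff))
  res <- stats::lm.fit(design, ts$data)$residuals
  parcel_ts(res, tr = ts$tr, fd = ts$fd, rms = ts$rms, flags = ts$flags)
}

# Backward differences, first row zero (preserves frame count).
backward_diff <- function(x) {
  x <- as.matrix(x)
  rbind(0, diff(x))
}

# Drop collinear columns of a design matrix (QR pivoting), with a warning.
prune_design <- function(design) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- qrd$pivot[-seq_len(qrd$rank)]
    warning(sprintf("dropping %d collinear nuisance column(s): %s",
                    length(drop), paste(drop, collapse = ", ")))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
  }
  design
}

#' Nuisance regression of parcel time series
#'
#' Replaces each parcel column by its OLS residual against an intercept,
#' the supplied nuisance regressors, their backward-difference first
#' derivatives (first row zero), and optionally the global mean signal
#' (mean across parcels) plus its derivative. Collinear design columns are
#' dropped with a warning.
#'
#' @param ts a [parcel_ts].
#' @param nuisance frames x R numeric matrix of nuisance signals (may be
#'   `NULL` when only global signal regression is wanted).
#' @param add_derivatives include backward-difference derivatives
#'   (default `TRUE`).
#' @param gsr include the global mean signal (default `TRUE`).
#' @return residualized `parcel_ts`.
#' @export
nuisance_regress <- function(ts, nuisance = NULL, add_derivatives = TRUE,
                             gsr = TRUE) {
  stopifnot(inherits(ts, "parcel_ts"))
  n <- n_frames(ts)
  regs <- NULL
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n)
      stop("nuisance row count must equal frame count")
    regs <- nuisance
  }
  if (gsr) regs <- cbind(regs, rowMeans(ts$data))
  if (!is.null(regs) && add_derivatives)
    regs <- cbind(regs, backward_diff(regs))
  design <- prune_design(cbind(1, regs))
  res <- stats::lm.fit(design, ts$data)$residuals
  parcel_ts(res, tr = ts$tr, fd = ts$fd, rms = ts$rms, flags = ts$flags)
}

#' Scrub and denoise one scan in a single joint regression
#'
#' Pipeline order: compute frame flags, scrub (possibly excluding the
#' subject), then regress out -- in one joint design -- the DCT low-
#' frequency drift basis, the nuisance regressors, their derivatives and
#' (optionally) the global signal. A joint regression avoids the partial
#' reintroduction of removed variance that sequential regressions can
#' cause.
#'
#' @inheritParams nuisance_regress
#' @inheritParams highpass
#' @inheritParams scrub
#' @return denoised `parcel_ts`, or a `subject_exclusion`.
#' @export
preprocess_session <- function(ts, nuisance = NULL, cutoff = 0.008,
                               add_derivatives = TRUE, gsr = TRUE,
                               max_flag_frac = 0.5, min_frames = 30L) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (is.null(ts$flags))
    ts$flags <- compute_frame_flags(ts$fd, ts$rms)
  scr <- scrub(ts, max_flag_frac = max_flag_frac, min_frames = min_frames)
  if (is_excluded(scr)) return(scr)
  n <- n_frames(scr)
  regs <- dct_lowfreq_basis(n, scr$tr, cutoff)
  base <- NULL
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) %in% c(n, n_frames(ts)))
    if (nrow(nuisance) == n_frames(ts) && n != n_frames(ts))
      nuisance <- nuisance[!ts$flags, , drop = FALSE]
    base <- nuisance
  }
  if (gsr) base <- cbind(base, rowMeans(scr$data))
  if (!is.null(base) && add_derivatives) base <- cbind(base, backward_diff(base))
  design <- prune_design(cbind(1, regs, base))
  res <- stats::lm.fit(design, scr$data)$residuals
  parcel_ts(res, tr = scr$tr, fd = scr$fd, rms = scr$rms, flags = scr$flags)
}

#' Fisher-z functional connectivity matrix
#'
#' Pearson correlation between every pair of parcels, Fisher r-to-z
#' transformed. `|r|` is clipped to `1 - 1e-7` before `atanh` so degenerate
#' pairs stay finite; the diagonal is stored as 0 and excluded from all
#' downstream statistics.
#'
#' @param ts a [parcel_ts] with at least 30 frames.
#' @return an `fc_matrix` (fields `z`, `n_frames_used`).
#' @export
fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  n <- n_frames(ts)
  if (n < 30L) stop("need at least 30 frames for a correlation matrix")
  sds <- apply(ts$data, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance parcel(s): %s",
                 paste(which(sds == 0), collapse = ", ")))
  r <- stats::cor(ts$data)
  clip <- 1 - 1e-7
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  structure(list(z = z, n_frames_used = n), class = "fc_matrix")
}

#' Global brain connectivity map from an FC matrix
#'
#' GBC at parcel x is the mean Fisher-z connectivity of x with every other
#' parcel (the self-connection is excluded: including `atanh(1)` would be
#' infinite).
#'
#' @param fc an `fc_matrix`.
#' @param subject_id,condition optional labels carried on the result.
#' @return a `gbc_map` (fields `values`, `subject_id`, `condition`).
#' @export
gbc <- function(fc, subject_id = NA_character_, condition = NA_character_) {
  stopifnot(inherits(fc, "fc_matrix"))
  z <- fc$z
  if (max(abs(z - t(z))) > 1e-10) stop("FC matrix must be symmetric")
  p <- nrow(z)
  values <- rowSums(z) / (p - 1)  # diagonal stored as 0
  structure(
    list(values = values, subject_id = subject_id, condition = condition),
    class = "gbc_map"
  )
}

#' @export
print.gbc_map <- function(x, ...) {
  cat(sprintf("gbc_map (%s, %s): %d parcels, mean %.4f\n",
              x$subject_id, x$condition, length(x$values), mean(x$values)))
  invisible(x)
}

#' Drug-minus-placebo GBC map
#'
#' @param drug,placebo `gbc_map`s over the same atlas for the same subject.
#' @return a `delta_gbc_map`.
#' @export
delta_gbc <- function(drug, placebo) {
  stopifnot(inherits(drug, "gbc_map"), inherits(placebo, "gbc_map"))
  if (length(drug$values) != length(placebo$values))
    stop("atlas mismatch between the two GBC maps")
  structure(
    list(values = drug$values - placebo$values,
         subject_id = drug$subject_id,
         condition = paste0(drug$condition, "-", placebo$condition)),
    class = c("delta_gbc_map", "gbc_map")
  )
}

#' Per-subject drug-minus-placebo GBC maps for a simulated study
#'
#' Runs every session of a [simulate_study] result through the full
#' preprocessing chain (flags, scrub, joint DCT + GSR regression), computes
#' GBC per condition and stacks the drug-minus-placebo maps.
#'
#' @param study a [simulate_study] result.
#' @param gsr,cutoff forwarded to [preprocess_session]. GSR defaults to
#'   off here: in the one-factor session generator the shared signal is
#'   the carrier of the planted connectivity structure, not an artifact,
#'   so global signal regression would remove the very signal the recovery
#'   tests plant (real acquisitions keep the [preprocess_session] default).
#' @return list with `maps` (subjects x parcels Delta-GBC matrix) and
#'   `scrub_report` (data frame: subject, flagged counts, excluded flag).
#' @export
study_delta_gbc <- function(study, gsr = FALSE, cutoff = 0.008) {
  subjects <- names(study$sessions)
  p <- nrow(study$atlas)
  maps <- matrix(NA_real_, length(subjects), p,
                 dimnames = list(subjects, study$atlas$parcel_id))
  report <- data.frame(
    subject = subjects, n_flagged_drug = NA_integer_,
    n_flagged_placebo = NA_integer_, excluded = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(subjects)) {
    ses <- study$sessions[[i]]
    per_cond <- lapply(ses, function(ts) {
      ts$flags <- compute_frame_flags(ts$fd, ts$rms)
      preprocess_session(ts, gsr = gsr, cutoff = cutoff)
    })
    report$n_flagged_drug[i] <- sum(compute_frame_flags(
      ses$drug$fd, ses$drug$rms))
    report$n_flagged_placebo[i] <- sum(compute_frame_flags(
      ses$placebo$fd, ses$placebo$rms))
    if (any(vapply(per_cond, is_excluded, logical(1)))) {
      report$excluded[i] <- TRUE
      next
    }
    g <- lapply(per_cond, function(ts) gbc(fc_matrix(ts)))
    maps[i, ] <- delta_gbc(g$drug, g$placebo)$values
  }
  list(maps = maps[!report$excluded, , drop = FALSE], scrub_report = report)
}
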
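# Plain-text (TSV) interchange formats for every object the pipeline
# consumes or produces. All writers round-trip through their readers.

#' @rdname deltagbc-io
#' @param atlas,path see Details.
#' @details `write_atlas` / `read_atlas`: parcel table (`parcel_id`,
#'   `hemisphere`, `network`, `klass`, `x`, `y`, `z`).
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname deltagbc-io
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$network <- factor(df$network, levels = unique(df$network))
  df$klass <- factor(df$klass, levels = c("association", "sensory"))
  class(df) <- c("parcel_atlas", "data.frame")
  validate_atlas(df)
  df
}

#' TSV readers and writers
#'
#' Tab-separated interchange for the pipeline's objects: the parcel atlas,
#' per-scan BOLD matrices (frames x parcels, header = parcel ids) with a
#' companion motion table (`frame`, `fd`, `rms`), subjects x items
#' behavior tables, gene-expression maps (`parcel_id`, `value`,
#' `differential_stability`) and generic subjects x parcels map matrices.
#'
#' @param ts a [parcel_ts]; `x` a matrix; `value`,`differential_stability`
#'   per-gene data; `tr` repetition time used on read.
#' @name deltagbc-io
#' @export
write_timeseries <- function(ts, path, motion_path = NULL) {
  stopifnot(inherits(ts, "parcel_ts"))
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(motion_path)) {
    utils::write.table(
      data.frame(frame = seq_len(n_frames(ts)), fd = ts$fd, rms = ts$rms),
      motion_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname deltagbc-io
#' @param motion_path optional motion-trace TSV path.
#' @export
read_timeseries <- function(path, tr, motion_path = NULL) {
  data <- as.matrix(utils::read.delim(path, check.names = FALSE))
  fd <- rms <- NULL
  if (!is.null(motion_path)) {
    mot <- utils::read.delim(motion_path)
    fd <- mot$fd
    rms <- mot$rms
  }
  parcel_ts(data, tr = tr, fd = fd, rms = rms)
}

#' @rdname deltagbc-io
#' @export
write_behavior <- function(x, path) {
  df <- data.frame(subject = rownames(x) %||% seq_len(nrow(x)),
                   as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname deltagbc-io
#' @export
read_behavior <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname deltagbc-io
#' @export
write_gene_map <- function(value, path, differential_stability = NA_real_) {
  utils::write.table(
    data.frame(parcel_id = seq_along(value), value = value,
               differential_stability = differential_stability),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname deltagbc-io
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path)
  structure(df$value, differential_stability = df$differential_stability[1L])
}

#' @rdname deltagbc-io
#' @export
write_map_matrix <- function(x, path) {
  write_behavior(x, path)
}

#' @rdname deltagbc-io
#' @export
read_map_matrix <- function(path) {
  read_behavior(path)
}
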
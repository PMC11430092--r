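#' Write / read a subject recording as delimited text plus JSON sidecar
#'
#' The parcel-by-sample matrix is stored as tab-separated text (one parcel
#' per row) at `<path>.tsv`; metadata (subject id, group, sampling rate,
#' seed, mode, and the ground-truth state sequence when present) goes to
#' `<path>.json`.
#'
#' @param rec A `subject_recording`.
#' @param path Path stem (without extension).
#' @return `write_recording` returns the path stem invisibly;
#'   `read_recording` returns a `subject_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "subject_recording"))
  utils::write.table(rec$parcel_series, paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               fs = rec$fs, mode = rec$mode, seed = rec$seed,
               n_parcels = nrow(rec$parcel_series),
               n_samples = ncol(rec$parcel_series),
               true_states = rec$true_states)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  mat <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  dimnames(mat) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(subject_id = meta$subject_id, group = meta$group,
                 fs = meta$fs, parcel_series = mat,
                 true_states = if (!is.null(meta$true_states))
                   as.integer(meta$true_states) else NULL,
                 mode = meta$mode, seed = meta$seed),
            class = "subject_recording")
}

#' Tidy per-subject feature table
#'
#' Flattens temporal and network-level spatial features of one subject
#' into the long format used by [compare_groups()] (columns `subject_id`,
#' `group`, `feature`, `value`). Feature names encode the family as a
#' prefix: `within_<net>`, `between_<a>-<b>`, `tmw_<net>`,
#' `tmb_<a>-<b>`, `fo_state<k>`, `lifetime_state<k>`,
#' `interval_state<k>`.
#'
#' @param subject_id,group Identifiers.
#' @param temporal A [temporal_features()] list.
#' @param connectivity Output of [subject_connectivity()] (or NULL).
#' @param tm_within,tm_between Transition magnitudes (or NULL).
#' @return Long-format data frame.
#' @export
feature_table <- function(subject_id, group, temporal,
                          connectivity = NULL,
                          tm_within = NULL, tm_between = NULL) {
  rows <- list()
  add <- function(nm, val) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject_id, group = group, feature = nm,
      value = as.numeric(val), stringsAsFactors = FALSE)
  }
  K <- length(temporal$fractional_occupancy)
  add(paste0("fo_state", seq_len(K)), temporal$fractional_occupancy)
  add(paste0("lifetime_state", seq_len(K)), temporal$mean_lifetime_s)
  add(paste0("interval_state", seq_len(K)), temporal$mean_interval_s)
  if (!is.null(connectivity)) {
    add(paste0("within_", names(connectivity$within)), connectivity$within)
    add(paste0("between_", names(connectivity$between)), connectivity$between)
  }
  if (!is.null(tm_within)) add(paste0("tmw_", names(tm_within)), tm_within)
  if (!is.null(tm_between)) add(paste0("tmb_", names(tm_between)), tm_between)
  do.call(rbind, rows)
}
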
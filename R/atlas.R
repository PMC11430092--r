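#' Parcel atlas with canonical network labels
#'
#' Constructs a parcellation of `n_parcels` cortical parcels grouped into the
#' seven canonical resting-state networks (visual, somatomotor, dorsal
#' attention, ventral attention, limbic, frontoparietal, default mode).
#' The default layout mirrors a 100-parcel, 7-network cortical parcellation;
#' network sizes can be overridden as long as every network keeps at least
#' two parcels (so that within-network connectivity means are defined).
#'
#' @param n_parcels Total number of parcels (default 100).
#' @param network_names Ordered character vector of network names.
#' @param network_sizes Optional integer vector (same length as
#'   `network_names`) of parcels per network; must sum to `n_parcels`.
#'   When `NULL`, a default allocation is used for 100 parcels and a
#'   proportional allocation otherwise.
#' @return An object of class `parcel_atlas`: a list with `n_parcels`,
#'   `network_names`, and `network_labels` (a factor of length `n_parcels`).
#' @examples
#' atlas <- parcel_atlas()
#' table(atlas$network_labels)
#' @export
parcel_atlas <- function(n_parcels = 100L,
                         network_names = c("VIN", "SMN", "DAN", "VAN",
                                           "LIN", "FPN", "DMN"),
                         network_sizes = NULL) {
  n_parcels <- as.integer(n_parcels)
  n_net <- length(network_names)
  if (anyDuplicated(network_names))
    stop("network_names must be unique")
  if (is.null(network_sizes)) {
    if (n_parcels == 100L && n_net == 7L) {
      network_sizes <- c(14L, 16L, 13L, 12L, 10L, 13L, 22L)
    } else {
      base <- rep(n_parcels %/% n_net, n_net)
      base[seq_len(n_parcels %% n_net)] <- base[seq_len(n_parcels %% n_net)] + 1L
      network_sizes <- base
    }
  }
  network_sizes <- as.integer(network_sizes)
  if (length(network_sizes) != n_net)
    stop("network_sizes must match network_names in length")
  if (sum(network_sizes) != n_parcels)
    stop("network_sizes must sum to n_parcels")
  if (any(network_sizes < 2L))
    stop("every network needs at least 2 parcels")
  labels <- factor(rep(network_names, times = network_sizes),
                   levels = network_names)
  structure(list(n_parcels = n_parcels,
                 network_names = network_names,
                 network_labels = labels),
            class = "parcel_atlas")
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat("<parcel_atlas> ", x$n_parcels, " parcels, ",
      length(x$network_names), " networks\n", sep = "")
  print(table(x$network_labels))
  invisible(x)
}

validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (length(atlas$network_labels) != atlas$n_parcels)
    stop("atlas labels do not cover every parcel")
  if (!setequal(levels(atlas$network_labels), atlas$network_names))
    stop("atlas label set does not equal network_names")
  if (any(table(atlas$network_labels) < 2L))
    stop("every network needs at least 2 parcels")
  invisible(atlas)
}

#' Read / write a parcel atlas as a two-column CSV
#'
#' The on-disk format is `parcel_id, network`, one row per parcel, parcel
#' order preserved.
#'
#' @param atlas A `parcel_atlas`.
#' @param path File path.
#' @return `write_atlas` returns `path` invisibly; `read_atlas` returns a
#'   `parcel_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  df <- data.frame(parcel_id = seq_len(atlas$n_parcels),
                   network = as.character(atlas$network_labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nets <- unique(df$network)
  atlas <- structure(list(n_parcels = nrow(df),
                          network_names = nets,
                          network_labels = factor(df$network, levels = nets)),
                     class = "parcel_atlas")
  validate_atlas(atlas)
}
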
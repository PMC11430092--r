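#' Declarative configuration of the full analysis pipeline
#'
#' Bundles every stage's parameters with their standard defaults: target
#' sampling rate 250 Hz, PCA retaining 95% of variance, candidate state
#' counts 3..12, 10000 bootstrap iterations for the backbone median,
#' disparity-filter threshold searched over \[0.001, 0.10\], and a minimum
#' state-window length of 25 samples (100 ms at 250 Hz).
#'
#' @param cohort A [cohort_config()] (used when `simulate = TRUE`).
#' @param simulate Generate the cohort with the synthetic generator
#'   (default TRUE); otherwise `recordings` must be supplied to
#'   [run_pipeline()].
#' @param fs_target Target sampling rate after anti-aliased downsampling.
#' @param orthogonalize Apply source-leakage correction. `NULL` (default)
#'   decides per recording: oscillatory signal input is orthogonalized
#'   (before envelope extraction, as in source-space leakage-correction
#'   practice — envelopes of orthogonalized signals retain genuine
#'   amplitude coupling); envelope-mode input is left alone, since
#'   leakage-free amplitude data has no shared signal to remove and
#'   orthogonalizing the envelopes themselves would annihilate the
#'   coupling under study.
#' @param orth_method Orthogonalization variant, see [orthogonalize()].
#' @param hmm A [hmm_config()].
#' @param run_selection Select the state count by averaged AIC/BIC before
#'   the group fit (default TRUE); when FALSE, `K_fixed` is used.
#' @param K_fixed State count used when selection is disabled.
#' @param min_window_len Minimum state-window length in samples.
#' @param run_backbone Apply the disparity-filter backbone to the
#'   state-wise connectivity matrices before network averaging.
#' @param n_iter_bootstrap Bootstrap iterations for the edge-weight median.
#' @param alpha An [alpha_search()].
#' @param comparisons List of group pairings (first group first).
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            simulate = TRUE,
                            fs_target = 250,
                            orthogonalize = NULL,
                            orth_method = "qr",
                            hmm = hmm_config(),
                            run_selection = TRUE,
                            K_fixed = 7L,
                            min_window_len = 25L,
                            run_backbone = TRUE,
                            n_iter_bootstrap = 10000L,
                            alpha = alpha_search(),
                            comparisons = list(c("OAC", "YAC"),
                                               c("OAC", "TCOA")),
                            seed = 1L) {
  structure(list(cohort = cohort, simulate = simulate,
                 fs_target = fs_target,
                 orthogonalize = orthogonalize,
                 orth_method = orth_method,
                 hmm = hmm, run_selection = run_selection,
                 K_fixed = as.integer(K_fixed),
                 min_window_len = as.integer(min_window_len),
                 run_backbone = run_backbone,
                 n_iter_bootstrap = as.integer(n_iter_bootstrap),
                 alpha = alpha, comparisons = comparisons,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Stages: simulate (or ingest) parcel recordings; convert to
#' orthogonalized amplitude envelopes; select the state count and fit one
#' group-level Gaussian HMM; decode per-subject state sequences; compute
#' temporal features and state-wise connectivity; optionally extract the
#' disparity-filter backbone over the pooled state-wise graphs; reduce to
#' network-level summaries; and run the group comparisons. Every stage is
#' deterministic given the config's master seed. When `out_dir` is given,
#' stage outputs are written as CSV/JSON together with a manifest of
#' content hashes.
#'
#' @param config A [pipeline_config()].
#' @param recordings Optional list of `subject_recording`s (required when
#'   `config$simulate` is FALSE).
#' @param out_dir Optional artifact directory.
#' @return List with `K`, `selection`, `group_fit` (model + sequences),
#'   `features` (tidy table), `state_fc` (per subject), `backbone`
#'   (M, alpha, retention counts) and `comparisons` (one result table per
#'   pairing).
#' @export
run_pipeline <- function(config, recordings = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  atlas <- config$cohort$atlas
  if (config$simulate) {
    recordings <- generate_cohort(config$cohort)
  }
  if (is.null(recordings) || !length(recordings))
    stop("stage 'simulate': no recordings available")

  # --- envelope stage -------------------------------------------------
  # leakage correction acts on the signals, before envelope extraction;
  # envelope-mode input (already amplitude data) is corrected only on
  # explicit request
  envs <- lapply(recordings, function(rec) {
    x <- rec$parcel_series
    if (rec$fs > config$fs_target)
      x <- downsample(x, rec$fs, config$fs_target)
    fs <- min(rec$fs, config$fs_target)
    oscillatory <- identical(rec$mode, "oscillatory")
    do_orth <- if (is.null(config$orthogonalize)) oscillatory else
      config$orthogonalize
    if (do_orth) x <- orthogonalize(x, method = config$orth_method)
    if (oscillatory) x <- hilbert_envelope(x, fs)
    x <- unclass(x)
    attr(x, "fs") <- fs
    x
  })
  fs <- attr(envs[[1L]], "fs")

  # --- state-model stage ----------------------------------------------
  selection <- NULL
  if (config$run_selection) {
    selection <- select_n_states(lapply(envs, t), config$hmm)
    K <- selection$K_star
  } else {
    K <- config$K_fixed
  }
  gcfg <- config$hmm
  gcfg$seed <- config$seed
  group_fit <- fit_group_hmm(envs, K, gcfg, fs = fs)

  # --- feature stage ---------------------------------------------------
  subj <- names(recordings)
  temporal <- lapply(subj, function(s)
    temporal_features(group_fit$sequences[[s]]))
  names(temporal) <- subj
  state_fc <- lapply(subj, function(s) {
    compute_state_fc(envs[[s]], segment_states(group_fit$sequences[[s]]),
                     K = K, min_len = config$min_window_len)
  })
  names(state_fc) <- subj

  # --- backbone stage --------------------------------------------------
  backbone <- NULL
  if (config$run_backbone) {
    pool_graphs <- list()
    owner <- list()
    for (s in subj) for (k in seq_len(K)) {
      m <- state_fc[[s]]$matrices[[k]]
      if (is.null(m) || any(is.na(m))) next
      g <- m; diag(g) <- 0
      pool_graphs[[length(pool_graphs) + 1L]] <- g
      owner[[length(owner) + 1L]] <- c(s, k)
    }
    pool <- aggregate_edges(pool_graphs)
    boot <- bootstrap_median(pool, config$n_iter_bootstrap,
                             seed = config$seed)
    opt <- optimize_alpha(pool_graphs, boot$M, config$alpha)
    filtered <- apply_backbone(pool_graphs, boot$M, opt$alpha_optimal)
    for (i in seq_along(filtered)) {
      s <- owner[[i]][1L]; k <- as.integer(owner[[i]][2L])
      f <- filtered[[i]]
      diag(f) <- 1
      state_fc[[s]]$matrices[[k]] <- f
    }
    backbone <- list(M = boot$M, n_iter = boot$n_iter,
                     alpha_optimal = opt$alpha_optimal, J = opt$J,
                     n_retained = attr(filtered, "n_retained"))
  }

  # --- network summaries -----------------------------------------------
  features <- do.call(rbind, lapply(subj, function(s) {
    tf <- temporal[[s]]
    conn <- subject_connectivity(state_fc[[s]],
                                 tf$fractional_occupancy, atlas)
    summaries <- lapply(state_fc[[s]]$matrices, function(m)
      if (is.null(m)) NULL else network_means(m, atlas))
    tm_w <- transition_magnitude(lapply(summaries, function(x) x$within),
                                 tf$transition_probs,
                                 tf$fractional_occupancy)
    tm_b <- transition_magnitude(lapply(summaries, function(x) x$between),
                                 tf$transition_probs,
                                 tf$fractional_occupancy)
    feature_table(s, recordings[[s]]$group, tf, conn, tm_w, tm_b)
  }))

  # --- stats stage ------------------------------------------------------
  comparisons <- lapply(config$comparisons, function(pr) {
    if (!all(pr %in% features$group)) return(NULL)
    compare_groups(features, pr)
  })
  names(comparisons) <- vapply(config$comparisons, paste, "",
                               collapse = "_vs_")

  result <- list(K = K, fs = fs, selection = selection,
                 group_fit = group_fit, temporal = temporal,
                 state_fc = state_fc, backbone = backbone,
                 features = features, comparisons = comparisons,
                 groups = vapply(recordings, function(r) r$group, ""),
                 atlas = atlas, config = config)
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  invisible(result)
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(out_dir, "features.csv")
  utils::write.csv(result$features, p, row.names = FALSE)
  paths <- c(paths, p)
  for (nm in names(result$comparisons)) {
    if (is.null(result$comparisons[[nm]])) next
    p <- file.path(out_dir, paste0("comparison_", nm, ".csv"))
    utils::write.csv(result$comparisons[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  log <- list(K = result$K, fs = result$fs,
              seed = result$config$seed,
              backbone = result$backbone,
              selection = if (!is.null(result$selection))
                list(K_star = result$selection$K_star,
                     mean_criterion = result$selection$mean_criterion))
  p <- file.path(out_dir, "pipeline_log.json")
  jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Group-average connectivity report
#'
#' Produces, per group, the subject-averaged state-occupancy-weighted
#' connectivity matrix, z-scored over its off-diagonal cells and ordered
#' by network, plus the comparison tables. When `out_dir` is given the
#' matrices are written as CSV and rendered as heatmaps (PDF).
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Optional output directory.
#' @return List with `matrices` (one z-scored N x N matrix per group) and
#'   `comparisons`.
#' @export
render_report <- function(result, out_dir = NULL) {
  atlas <- result$atlas
  N <- atlas$n_parcels
  groups <- unique(result$groups)
  mats <- lapply(groups, function(g) {
    subj <- names(result$groups)[result$groups == g]
    acc <- matrix(0, N, N); nacc <- 0L
    for (s in subj) {
      fo <- result$temporal[[s]]$fractional_occupancy
      pres <- which(!vapply(result$state_fc[[s]]$matrices, is.null,
                            logical(1)) & fo > 0)
      if (!length(pres)) next
      w <- fo[pres] / sum(fo[pres])
      m <- Reduce(`+`, Map(function(k, wk) wk * result$state_fc[[s]]$matrices[[k]],
                           pres, w))
      acc <- acc + m; nacc <- nacc + 1L
    }
    m <- acc / nacc
    off <- row(m) != col(m)
    m[off] <- (m[off] - mean(m[off])) / stats::sd(m[off])
    diag(m) <- 0
    m
  })
  names(mats) <- groups
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in groups) {
      utils::write.csv(mats[[g]],
                       file.path(out_dir, paste0("fc_", g, ".csv")),
                       row.names = FALSE)
    }
    pdf_path <- file.path(out_dir, "fc_matrices.pdf")
    grDevices::pdf(pdf_path, width = 6, height = 5.5)
    on.exit(grDevices::dev.off())
    for (g in groups) print(fc_heatmap(mats[[g]], atlas, title = g))
    }
  list(matrices = mats, comparisons = result$comparisons)
}

#' Heatmap of a parcel-level connectivity matrix ordered by network
#'
#' @param mat N x N matrix (parcels in atlas order).
#' @param atlas A [parcel_atlas()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
fc_heatmap <- function(mat, atlas, title = "") {
  N <- atlas$n_parcels
  df <- expand.grid(row = seq_len(N), col = seq_len(N))
  df$value <- as.vector(mat)
  bounds <- cumsum(table(atlas$network_labels))
  mids <- bounds - diff(c(0, bounds)) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::scale_y_reverse(breaks = mids,
                             labels = atlas$network_names) +
    ggplot2::scale_x_continuous(breaks = mids,
                                labels = atlas$network_names) +
    ggplot2::geom_hline(yintercept = bounds[-length(bounds)] + 0.5,
                        linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = bounds[-length(bounds)] + 0.5,
                        linewidth = 0.2) +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal()
}
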
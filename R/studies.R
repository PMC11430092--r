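#' State-count recovery study
#'
#' Replicated model-order selection on synthetic envelope cohorts drawn
#' from the generator's default ground truth: per replicate, `n_subjects`
#' envelope recordings are simulated, each is PCA-reduced per subject, and
#' Gaussian HMMs over `cfg$K_range` are scored; the replicate's selected
#' state count minimizes the across-subject mean of `(AIC + BIC)/2`. The
#' study reports every replicate's selection and the modal choice.
#'
#' The default problem size (10 subjects of 60 s at 250 Hz, PCA capped at
#' 20 dimensions, single EM start per fit) keeps one replicate around a
#' minute and a half on one CPU while leaving the selection curve's
#' minimum well resolved.
#'
#' @param base_seeds One master seed per replicate.
#' @param n_subjects Subjects per replicate.
#' @param duration_s,fs Recording length (s) and sampling rate (Hz).
#' @param model A [ground_truth_model()]; default ground truth.
#' @param cfg A [hmm_config()] for selection.
#' @return List with `K_stars` (one per replicate), `K_modal`, and the
#'   per-replicate mean criterion curves.
#' @export
state_count_study <- function(base_seeds = 1000:1009,
                              n_subjects = 10L,
                              duration_s = 60, fs = 250,
                              model = ground_truth_model(),
                              cfg = hmm_config(K_range = 3:12,
                                               pca_retained = 0.95,
                                               pca_max_dims = 20,
                                               n_restarts = 1L,
                                               em_max_iter = 25L,
                                               em_tol = 1e-4)) {
  atlas <- model$atlas
  K_stars <- integer(length(base_seeds))
  curves <- vector("list", length(base_seeds))
  for (r in seq_along(base_seeds)) {
    base <- base_seeds[r]
    datasets <- lapply(seq_len(n_subjects), function(s)
      t(generate_recording(atlas, model, duration_s, fs,
                           seed = base * 100 + s)$parcel_series))
    rcfg <- cfg
    rcfg$seed <- base
    sel <- suppressWarnings(select_n_states(datasets, rcfg))
    K_stars[r] <- sel$K_star
    curves[[r]] <- sel$mean_criterion
  }
  tab <- table(K_stars)
  list(K_stars = K_stars,
       K_modal = as.integer(names(tab)[which.max(tab)]),
       curves = curves)
}

#' Group-ordering recovery study
#'
#' Runs the full pipeline on replicated synthetic cohorts whose
#' connectivity levels are scaled `TCOA > YAC > OAC` (the generator's
#' default group effects) and checks, per replicate, that (i) the group
#' medians of subject-level mean within-network and mean between-network
#' connectivity reproduce that ordering and (ii) the rank-biserial
#' correlation of OAC versus each other group is negative for both
#' feature families. Recordings are deliberately short (the group effects
#' are large relative to subject-level estimation noise, which the study
#' verifies rather than assumes).
#'
#' @param replicates Number of replicated cohorts.
#' @param base_seed Seed offset; replicate r uses `base_seed + r`.
#' @param duration_s,fs Per-subject recording length and sampling rate.
#' @param K_fixed State count for the group HMM fit.
#' @return Data frame with one row per replicate: ordering and sign
#'   indicators per family, and an overall `pass` flag.
#' @export
ordering_study <- function(replicates = 20L, base_seed = 100L,
                           duration_s = 15, fs = 125, K_fixed = 7L) {
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    seed <- base_seed + r
    config <- pipeline_config(
      cohort = cohort_config(duration_s = duration_s, fs = fs, seed = seed),
      fs_target = fs,
      hmm = hmm_config(n_restarts = 1L, em_max_iter = 12L, em_tol = 1e-3,
                       pca_max_dims = 20, seed = seed),
      run_selection = FALSE, K_fixed = K_fixed,
      min_window_len = max(5L, as.integer(round(0.1 * fs))),
      n_iter_bootstrap = 100L,
      alpha = alpha_search(grid_step = 0.005),
      seed = seed)
    res <- run_pipeline(config)
    f <- res$features
    row <- list(replicate = r)
    pass <- TRUE
    for (fam in c("within", "between")) {
      sub <- f[grepl(paste0("^", fam, "_"), f$feature), ]
      sm <- stats::aggregate(value ~ subject_id + group, data = sub,
                             FUN = mean)
      med <- tapply(sm$value, sm$group, stats::median)
      ordered <- med["TCOA"] > med["YAC"] && med["YAC"] > med["OAC"]
      r_neg <- TRUE
      for (other in c("YAC", "TCOA")) {
        x <- sm$value[sm$group == "OAC"]
        y <- sm$value[sm$group == other]
        rb <- rank_biserial(mannwhitney_u(x, y), length(x), length(y))
        row[[paste0("r_", fam, "_", other)]] <- rb
        if (rb >= 0) r_neg <- FALSE
      }
      row[[paste0("ordered_", fam)]] <- ordered
      pass <- pass && ordered && r_neg
    }
    row$pass <- pass
    out[[r]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}
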
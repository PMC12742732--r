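# End-to-end synthetic study: subject-level trial and EEG simulation with a
# built-in (negative) coupling between total time binding and high-order
# topological complexity, the full preprocessing + feature stack, and the
# nonparametric statistical battery.

#' Configuration of a synthetic end-to-end study
#'
#' Defaults mirror the study conditions: three groups (SCR, SLR, CTR)
#' with total-time-binding means 123/51/82 ms and SDs 75/41/54 ms, 20
#' trials per condition with 70 ms Gaussian judgment noise, 256 Hz
#' 4-channel EEG with eight 30 s reflection questions (SCR/SLR) or one
#' 240 s block (CTR), and TDA at 64 Hz after decimation by 4.  Problem-
#' size knobs (`n_per_group`, `n_questions`, `fs`, `subsample_to`,
#' `features`) exist so that reduced but structurally identical studies
#' can be run quickly.
#'
#' When `couple_entropy_to_ttb` is on, each subject's EEG regularity is
#' tied to their true binding score: larger TTB yields a more oscillatory
#' (less broadband) signal, whose embedded point cloud carries less
#' topological complexity -- inducing a negative TTB vs Hodge-entropy
#' correlation with strength governed by `coupling_strength`.
#'
#' @param n_per_group subjects per group
#' @param groups group labels
#' @param ttb_mean_ms,ttb_sd_ms named per-group true TTB mean / SD (ms)
#' @param judgment_noise_sd_ms per-trial judgment noise (ms)
#' @param n_trials_per_condition trials per condition
#' @param clock_period_ms Libet clock period (ms)
#' @param fs EEG sampling rate (Hz)
#' @param n_questions reflection questions per session
#' @param question_s question duration (s)
#' @param ica_screen run the muscle-component screener per subject
#' @param muscle_artifact inject a muscle artifact (exercises the screener)
#' @param downsample_factor decimation factor before TDA
#' @param couple_entropy_to_ttb logical, see above
#' @param coupling_strength dimensionless coupling gain (default 0.4)
#' @param features subset of c("spectral", "tda", "hodge", "mse")
#' @param embed_m,embed_tau embedding dimension / delay (`NULL` = auto)
#' @param subsample_to maximum embedded cloud size
#' @param max_dim largest homology dimension for persistence
#' @param hodge_orders Hodge Laplacian orders to evaluate
#' @param hodge_alpha damping factor
#' @param hodge_radius_mult Hodge filtration scale as a multiple of the
#'   1-skeleton connectivity radius (default 1.5: at the bare connectivity
#'   radius the 2-skeleton is barely populated and its spectrum is
#'   uninformative; see the methods vignette)
#' @param welch_window_s Welch window (s)
#' @param mse_scales multiscale-entropy scale factors
#' @param holm_correction apply Holm correction to the reported p-values
#'   (off by default, matching a pilot-style analysis; the manifest states
#'   which mode ran)
#' @param seed master seed
#' @return object of class `study_config`
#' @export
study_config <- function(n_per_group = 10,
                         groups = c("SCR", "SLR", "CTR"),
                         ttb_mean_ms = c(SCR = 123, SLR = 51, CTR = 82),
                         ttb_sd_ms = c(SCR = 75, SLR = 41, CTR = 54),
                         judgment_noise_sd_ms = 70,
                         n_trials_per_condition = 20,
                         clock_period_ms = 2560,
                         fs = 256,
                         n_questions = 8,
                         question_s = 30,
                         ica_screen = FALSE,
                         muscle_artifact = FALSE,
                         downsample_factor = 4,
                         couple_entropy_to_ttb = TRUE,
                         coupling_strength = 0.4,
                         features = c("spectral", "tda", "hodge", "mse"),
                         embed_m = 3, embed_tau = NULL,
                         subsample_to = 100,
                         max_dim = 2,
                         hodge_orders = 0:2,
                         hodge_alpha = 1,
                         hodge_radius_mult = 1.5,
                         welch_window_s = 4,
                         mse_scales = 1:20,
                         holm_correction = FALSE,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (n_per_group < 2) stop_invalid("need at least 2 subjects per group")
  if (!all(groups %in% names(ttb_mean_ms)) || !all(groups %in% names(ttb_sd_ms)))
    stop_invalid("ttb_mean_ms / ttb_sd_ms must name every group")
  structure(cfg, class = "study_config")
}

#' EEG generator settings for one simulated subject
#'
#' Maps a subject's true total time binding onto an EEG "irregularity"
#' in (0, 1) -- 0 being strongly oscillatory (dominant alpha rhythm), 1
#' broadband -- centred on the grand mean of the group TTB means (85 ms)
#' with a 60 ms scale.  Larger TTB gives a more regular signal, whose
#' delay-embedded cloud carries less high-order topological complexity;
#' this is the built-in negative TTB / Hodge-entropy coupling.
#'
#' @param cfg a [study_config()]
#' @param true_ttb the subject's true total binding (ms)
#' @param duration_s recording duration (s)
#' @param seed subject-level seed
#' @return an [eeg_sim_config()]
#' @export
subject_eeg_config <- function(cfg, true_ttb, duration_s, seed) {
  irr <- if (cfg$couple_entropy_to_ttb)
    min(0.95, max(0.05, 0.5 - cfg$coupling_strength * (true_ttb - 85) / 60))
  else 0.5
  eeg_sim_config(
    duration_s = duration_s, fs = cfg$fs,
    band_weights = c(delta = 0.3, theta = 0.2,
                     alpha = 0.2 + 1.6 * (1 - irr),
                     sigma = 0.05, beta = 0.1, gamma = 0.05),
    one_over_f_amp = 0.3 + 1.2 * irr,
    line_noise_amp = if (cfg$fs / 2 > 50) 0.2 else 0,
    muscle_artifact = cfg$muscle_artifact,
    muscle_amplitude = if (cfg$muscle_artifact) 5 else 0,
    seed = seed)
}

# all scalar features of one downsampled condition segment
segment_features <- function(seg_native, cfg) {
  out <- list()
  if ("spectral" %in% cfg$features) {
    ps <- welch_psd(seg_native, window_s = cfg$welch_window_s)
    rbp <- relative_band_power(ps)
    for (b in names(rbp)) out[[paste0("rbp_", b)]] <- rbp[[b]]
  }
  seg <- downsample_segment(seg_native, cfg$downsample_factor)
  need_cloud <- any(c("tda", "hodge") %in% cfg$features)
  if (need_cloud) {
    cloud <- takens_embed(seg$samples, m = cfg$embed_m, tau = cfg$embed_tau,
                          subsample_to = cfg$subsample_to)
    if ("tda" %in% cfg$features) {
      diag <- vr_persistence(cloud, max_dim = cfg$max_dim)
      for (k in 0:cfg$max_dim) {
        out[[paste0("pe_", k)]] <- suppressWarnings(persistence_entropy(diag, k))
        out[[paste0("amp_", k)]] <- persistence_amplitude(diag, k)
      }
    }
    if ("hodge" %in% cfg$features) {
      radius <- cfg$hodge_radius_mult * rips_connectivity_radius(cloud)
      for (ord in cfg$hodge_orders) {
        val <- tryCatch({
          spec <- build_hodge_laplacian(cloud, order = ord, radius = radius)
          hodge_spectral_entropy(spec, alpha = cfg$hodge_alpha)
        }, error = function(e) NA_real_)
        out[[paste0("hse_", ord)]] <- val
      }
    }
  }
  if ("mse" %in% cfg$features) {
    seg_mse <- if (need_cloud) seg else downsample_segment(seg_native, cfg$downsample_factor)
    mse <- multiscale_entropy(seg_mse$samples, scales = cfg$mse_scales)
    out$mse_mean <- mean(mse$sampen, na.rm = TRUE)
    out$mse_scale1 <- mse$sampen[1]
  }
  unlist(out)
}

# feature vector of one subject: per-channel averages over questions
subject_features <- function(rec, group, cfg) {
  if (cfg$ica_screen) rec <- screen_components(rec)$cleaned
  pooled <- pool_channels(rec)
  total_s <- cfg$n_questions * cfg$question_s
  segs <- extract_segments(pooled, group, question_s = cfg$question_s,
                           total_s = total_s)
  rows <- list()
  for (ch in c("TP", "AF")) {
    ch_segs <- Filter(function(s) s$channel == ch, segs)
    per_q <- lapply(ch_segs, segment_features, cfg = cfg)
    rows[[ch]] <- average_over_questions(per_q)
  }
  rows
}

#' Run the full synthetic study pipeline
#'
#' Simulates every subject's Libet-clock trials and EEG session, applies
#' preprocessing (band-pass + notch, optional component screening,
#' pooling, segmentation, decimation), extracts the configured features,
#' scores intentional binding, and runs the statistical battery:
#' Shapiro-Wilk gating, one-tailed Mann-Whitney comparisons
#' (SCR > SLR, SLR < CTR, SCR > CTR) on total binding, the Kruskal-Wallis
#' omnibus with epsilon-squared, per-feature Kruskal-Wallis tests, and
#' Pearson correlations between total binding and the Hodge spectral
#' entropies.  Deterministic given `config$seed`.
#'
#' @param config a [study_config()]
#' @param out_dir optional directory: writes the binding table, feature
#'   table, test tables and a JSON run manifest
#' @return list with `scores`, `binding_table`, `ttb_tests`,
#'   `feature_table`, `feature_tests`, `correlations`, `manifest`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  n_subj <- cfg$n_per_group * length(cfg$groups)
  draws <- with_local_seed(cfg$seed, {
    list(seeds = matrix(sample.int(.Machine$integer.max - 1, 2 * n_subj),
                        ncol = 2),
         ttb_z = rnorm(n_subj))
  })
  scores <- list(); feat_rows <- list()
  idx <- 0
  for (g in cfg$groups) {
    for (s in seq_len(cfg$n_per_group)) {
      idx <- idx + 1
      sid <- sprintf("%s_%02d", g, s)
      true_ttb <- cfg$ttb_mean_ms[[g]] + cfg$ttb_sd_ms[[g]] * draws$ttb_z[idx]
      trials <- generate_trials(trial_sim_config(
        n_trials_per_condition = cfg$n_trials_per_condition,
        clock_period_ms = cfg$clock_period_ms,
        action_shift_ms = true_ttb / 2, tone_shift_ms = -true_ttb / 2,
        judgment_noise_sd_ms = cfg$judgment_noise_sd_ms,
        seed = draws$seeds[idx, 1]))
      sc <- binding_scores(trials, subject = sid)
      sc$group <- g
      sc$true_ttb <- true_ttb
      scores[[idx]] <- sc
      duration_s <- cfg$n_questions * cfg$question_s
      events <- if (g == "CTR") NULL else
        make_question_events(cfg$n_questions, cfg$question_s, cfg$fs)
      rec <- generate_eeg(subject_eeg_config(cfg, true_ttb, duration_s,
                                             draws$seeds[idx, 2]),
                          events = events)
      rec <- bandpass_notch(rec, filter_spec())
      feats <- subject_features(rec, g, cfg)
      for (ch in names(feats)) {
        v <- feats[[ch]]
        feat_rows[[length(feat_rows) + 1]] <- data.frame(
          subject = sid, group = g, channel = ch,
          feature = names(v), value = unname(v))
      }
    }
  }
  scores <- do.call(rbind, scores)
  feature_table <- do.call(rbind, feat_rows)

  ttb_by_group <- split(scores$total_binding_ms, scores$group)[cfg$groups]
  mw <- list(
    SCR_gt_SLR = mann_whitney_one_tailed(ttb_by_group$SCR, ttb_by_group$SLR,
                                         "greater", "SCR > SLR"),
    SLR_lt_CTR = mann_whitney_one_tailed(ttb_by_group$SLR, ttb_by_group$CTR,
                                         "less", "SLR < CTR"),
    SCR_gt_CTR = mann_whitney_one_tailed(ttb_by_group$SCR, ttb_by_group$CTR,
                                         "greater", "SCR > CTR"))
  mw_p <- maybe_holm(vapply(mw, `[[`, numeric(1), "p_value"), cfg$holm_correction)
  ttb_tests <- list(shapiro = shapiro_gate(ttb_by_group),
                    kruskal = kruskal_wallis_epsilon2(ttb_by_group),
                    mann_whitney = mw, mann_whitney_p = mw_p)

  feature_tests <- NULL
  if (nrow(feature_table)) {
    combos <- unique(feature_table[, c("channel", "feature")])
    feature_tests <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      sub <- feature_table[feature_table$channel == combos$channel[i] &
                           feature_table$feature == combos$feature[i], ]
      if (any(is.na(sub$value))) return(NULL)
      kw <- kruskal_wallis_epsilon2(split(sub$value, sub$group)[cfg$groups])
      data.frame(channel = combos$channel[i], feature = combos$feature[i],
                 H = kw$statistic, p = kw$p_value, epsilon2 = kw$effect_size,
                 magnitude = kw$magnitude)
    }))
    if (!is.null(feature_tests))
      feature_tests$p_reported <- maybe_holm(feature_tests$p, cfg$holm_correction)
  }

  correlations <- NULL
  hse_feats <- unique(grep("^hse_", feature_table$feature, value = TRUE))
  if (length(hse_feats)) {
    correlations <- do.call(rbind, lapply(c("TP", "AF"), function(ch) {
      do.call(rbind, lapply(hse_feats, function(f) {
        sub <- feature_table[feature_table$channel == ch &
                             feature_table$feature == f, ]
        m <- merge(scores[, c("subject", "total_binding_ms")], sub, by = "subject")
        if (nrow(m) < 3 || any(is.na(m$value))) return(NULL)
        pc <- pearson_corr(m$total_binding_ms, m$value, pair = c("TTB", f))
        data.frame(channel = ch, feature = f, r = pc$r, p = pc$p_value, n = pc$n)
      }))
    }))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("topobind")),
    r_version = R.version.string,
    seed = cfg$seed,
    binding_convention = binding_convention(),
    multiple_comparison_correction = if (cfg$holm_correction) "holm" else "none",
    config = cfg[setdiff(names(cfg), "")])

  bundle <- list(scores = scores, binding_table = group_binding_table(scores),
                 ttb_tests = ttb_tests, feature_table = feature_table,
                 feature_tests = feature_tests, correlations = correlations,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(scores, file.path(out_dir, "binding_scores.csv"), row.names = FALSE)
    write.csv(bundle$binding_table, file.path(out_dir, "binding_table.csv"),
              row.names = FALSE)
    write.csv(feature_table, file.path(out_dir, "feature_table.csv"),
              row.names = FALSE)
    if (!is.null(feature_tests))
      write.csv(feature_tests, file.path(out_dir, "feature_tests.csv"),
                row.names = FALSE)
    if (!is.null(correlations))
      write.csv(correlations, file.path(out_dir, "correlations.csv"),
                row.names = FALSE)
    mwdf <- data.frame(comparison = names(mw),
                       U = vapply(mw, `[[`, numeric(1), "statistic"),
                       p = vapply(mw, `[[`, numeric(1), "p_value"),
                       p_reported = mw_p)
    write.csv(mwdf, file.path(out_dir, "ttb_mann_whitney.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  bundle
}

#' A reduced study configuration for quick end-to-end runs
#'
#' Structurally identical to the full design (same groups, effects, noise
#' levels and coupling) at a smaller problem size: fewer subjects, one
#' 30 s question, 128 Hz acquisition decimated by 2, 40-point clouds, and
#' only the order-2 Hodge entropy feature.
#'
#' @param n_per_group subjects per group (default 5)
#' @param seed master seed
#' @param ... overrides passed on to [study_config()]
#' @return a [study_config()]
#' @export
mini_study_config <- function(n_per_group = 5, seed = 1L, ...) {
  args <- list(n_per_group = n_per_group, fs = 128, n_questions = 1,
               question_s = 30, downsample_factor = 2, subsample_to = 40,
               features = "hodge", hodge_orders = 2, mse_scales = 1:5,
               seed = seed)
  do.call(study_config, modifyList(args, list(...)))
}
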
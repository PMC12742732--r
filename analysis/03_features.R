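#!/usr/bin/env Rscript
# Stage 3 -- feature extraction.
#
# Per segment: six-band relative band power (Welch), then after decimation
# to 64 Hz a Takens embedding (m = 3, delay from the first minimum of
# time-delayed mutual information, farthest-point subsampling), Rips
# persistence features (persistence entropy and Wasserstein amplitude for
# H0..H2), Hodge spectral entropies of orders 0..2 at 1.5x the
# connectivity radius, and multiscale sample entropy.  Per-question
# features are averaged per subject and channel.
# Reads results/raw + results/segments, writes results/feature_table.csv.

library(topobind)

subjects <- read.csv(file.path("results", "raw", "subjects.csv"))
segdir <- file.path("results", "segments")
cfg <- mini_study_config(n_per_group = 5, seed = 101,
                         features = c("spectral", "tda", "hodge", "mse"),
                         hodge_orders = 0:2)

rows <- list()
for (i in seq_len(nrow(subjects))) {
  sid <- subjects$subject[i]
  for (ch in c("TP", "AF")) {
    files <- list.files(segdir, pattern = paste0("^", sid, "_", ch, "_q"),
                        full.names = TRUE)
    per_q <- lapply(files, function(f) {
      seg <- condition_segment(read.csv(f)$sample, subjects$fs[i],
                               subjects$group[i], ch)
      feats <- list()
      rbp <- relative_band_power(welch_psd(seg))
      for (b in names(rbp)) feats[[paste0("rbp_", b)]] <- rbp[[b]]
      dseg <- downsample_segment(seg, cfg$downsample_factor)
      cloud <- takens_embed(dseg$samples, m = cfg$embed_m,
                            subsample_to = cfg$subsample_to)
      diag <- vr_persistence(cloud, max_dim = 2)
      for (k in 0:2) {
        feats[[paste0("pe_", k)]] <- suppressWarnings(persistence_entropy(diag, k))
        feats[[paste0("amp_", k)]] <- persistence_amplitude(diag, k)
      }
      radius <- cfg$hodge_radius_mult * rips_connectivity_radius(cloud)
      for (ord in 0:2) {
        feats[[paste0("hse_", ord)]] <- tryCatch(
          hodge_spectral_entropy(build_hodge_laplacian(cloud, ord, radius)),
          error = function(e) NA_real_)
      }
      mse <- multiscale_entropy(dseg$samples, scales = cfg$mse_scales)
      feats$mse_mean <- mean(mse$sampen, na.rm = TRUE)
      unlist(feats)
    })
    avg <- average_over_questions(per_q)
    rows[[length(rows) + 1]] <- data.frame(
      subject = sid, group = subjects$group[i], channel = ch,
      feature = names(avg), value = unname(avg))
  }
}
ft <- do.call(rbind, rows)
write.csv(ft, file.path("results", "feature_table.csv"), row.names = FALSE)
cat("feature table:", nrow(ft), "rows,",
    length(unique(ft$feature)), "features x",
    length(unique(ft$subject)), "subjects x 2 channels\n")
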
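#!/usr/bin/env Rscript
# Stage 5 -- statistical battery.
#
# Shapiro-Wilk gating of the binding measures, the one-tailed Mann-Whitney
# comparisons (SCR > SLR, SLR < CTR, SCR > CTR) on total binding, the
# Kruskal-Wallis omnibus with epsilon-squared, per-feature Kruskal-Wallis
# tests, Pearson correlations between total binding and the Hodge spectral
# entropies, and the Wilcoxon power analysis.  No multiple-comparison
# correction is applied (pilot-style analysis); re-run with Holm via
# maybe_holm() if desired.
# Reads results/binding_scores.csv + results/feature_table.csv,
# writes results/stats/.

library(topobind)

out <- file.path("results", "stats")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
scores <- read.csv(file.path("results", "binding_scores.csv"))
ft <- read.csv(file.path("results", "feature_table.csv"))
groups <- c("SCR", "SLR", "CTR")
ttb <- split(scores$total_binding_ms, scores$group)[groups]

cat("== normality gate (total binding) ==\n")
print(shapiro_gate(ttb))

kw <- kruskal_wallis_epsilon2(ttb)
cat("\n== omnibus ==\n"); print(kw)

mw <- list(SCR_gt_SLR = mann_whitney_one_tailed(ttb$SCR, ttb$SLR, "greater", "SCR > SLR"),
           SLR_lt_CTR = mann_whitney_one_tailed(ttb$SLR, ttb$CTR, "less", "SLR < CTR"),
           SCR_gt_CTR = mann_whitney_one_tailed(ttb$SCR, ttb$CTR, "greater", "SCR > CTR"))
cat("\n== one-tailed Mann-Whitney on total binding ==\n")
for (m in mw) print(m)
write.csv(data.frame(comparison = names(mw),
                     U = sapply(mw, `[[`, "statistic"),
                     p = sapply(mw, `[[`, "p_value")),
          file.path(out, "ttb_mann_whitney.csv"), row.names = FALSE)

cat("\n== per-feature Kruskal-Wallis ==\n")
combos <- unique(ft[, c("channel", "feature")])
feat_tests <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
  sub <- ft[ft$channel == combos$channel[i] & ft$feature == combos$feature[i], ]
  if (any(is.na(sub$value))) return(NULL)
  k <- kruskal_wallis_epsilon2(split(sub$value, sub$group)[groups])
  data.frame(channel = combos$channel[i], feature = combos$feature[i],
             H = k$statistic, p = k$p_value, epsilon2 = k$effect_size,
             magnitude = k$magnitude)
}))
write.csv(feat_tests, file.path(out, "feature_tests.csv"), row.names = FALSE)
print(head(feat_tests[order(feat_tests$p), ], 10))

cat("\n== TTB vs Hodge spectral entropy ==\n")
cors <- do.call(rbind, lapply(c("TP", "AF"), function(ch) {
  do.call(rbind, lapply(grep("^hse_", unique(ft$feature), value = TRUE), function(f) {
    sub <- merge(scores[, c("subject", "total_binding_ms")],
                 ft[ft$channel == ch & ft$feature == f, ], by = "subject")
    if (any(is.na(sub$value))) return(NULL)
    pc <- pearson_corr(sub$total_binding_ms, sub$value, pair = c("TTB", f))
    data.frame(channel = ch, feature = f, r = pc$r, p = pc$p_value, n = pc$n)
  }))
}))
write.csv(cors, file.path(out, "correlations.csv"), row.names = FALSE)
print(cors)

cat("\n== power analysis (paired Wilcoxon, d = 0.6, alpha = .05, power = .95) ==\n")
pw <- wilcoxon_power_n(0.6, n_sims = 2000, seed = 1)
cat("ARE route: n =", pw$n_are, "; simulation route: n =", pw$n_sim, "\n")
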
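#!/usr/bin/env Rscript
# Stage 4 -- intentional binding scores.
#
# Converts each subject's Libet-clock judgments to signed millisecond
# errors, computes action / tone / total binding against the single-event
# baselines, and tabulates group means (SD).
# Reads results/raw/, writes results/binding_scores.csv and
# results/binding_table.csv.

library(topobind)

subjects <- read.csv(file.path("results", "raw", "subjects.csv"))
scores <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
  sid <- subjects$subject[i]
  trials <- read.csv(file.path("results", "raw", paste0("trials_", sid, ".csv")))
  sc <- binding_scores(trials, subject = sid)
  sc$group <- subjects$group[i]
  sc
}))
write.csv(scores, file.path("results", "binding_scores.csv"), row.names = FALSE)
tab <- group_binding_table(scores)
write.csv(tab, file.path("results", "binding_table.csv"), row.names = FALSE)

cat("sign convention:", binding_convention(), "\n\n")
tot <- tab[tab$measure == "total", ]
for (i in seq_len(nrow(tot)))
  cat(sprintf("%s total binding: %6.1f (%.1f) ms, n = %d\n",
              tot$group[i], tot$mean[i], tot$sd[i], tot$n[i]))
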
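#!/usr/bin/env Rscript
# Simulate the scoring study: 26 lavage samples, each contributing one
# Prussian-blue and one Turnbull-blue slide (52 slides), with every alveolar
# macrophage carried as a ground-truth annotation and per-slide lavage
# chemistry (iron censored below 0.4 umol/L; RBC and hemoglobin independent
# of the score). Downstream scripts read the study object from scratch/.

library(hemoscore)

seed <- 1
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

study <- generate_study(study_config(), seed = seed)
study$manifests <- simulate_study_chemistry(study, seed = seed)
saveRDS(list(study = study, seed = seed), "scratch/study.rds")

write.csv(study$manifests, "results/manifests.csv", row.names = FALSE)

gt_ths <- tapply(study$cells$grade, study$cells$slide_id,
                 function(g) 100 * mean(g))
cat(sprintf("slides: %d (%d per stain)\n", nrow(study$manifests),
            sum(study$manifests$stain == "prussian_blue")))
cat(sprintf("macrophages per slide: %d-%d (median %d), %d total\n",
            min(study$manifests$n_macrophages),
            max(study$manifests$n_macrophages),
            as.integer(median(study$manifests$n_macrophages)),
            nrow(study$cells)))
cat(sprintf("ground-truth THS: %.1f-%.1f (median %.1f), %d/%d slides EIPH+\n",
            min(gt_ths), max(gt_ths), median(gt_ths),
            sum(gt_ths >= 75), length(gt_ths)))
cat(sprintf("iron: %.2f-%.2f umol/L, %d slides censored (< 0.4)\n",
            min(study$manifests$iron), max(study$manifests$iron),
            sum(study$manifests$iron_censored)))
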
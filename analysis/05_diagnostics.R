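#!/usr/bin/env Rscript
# Diagnostic accuracy of the annotators' EIPH calls against the ground-truth
# THS and the mean annotators' THS, consensus across the panel, rank
# correlations with lavage chemistry, and the assembled study report.

library(hemoscore)

st <- readRDS("scratch/study.rds")
study <- st$study
matching <- readRDS("scratch/matching.rds")
ths_raw <- read_ths_table("results/ths_raw.csv")
ths_std <- read_ths_table("results/ths_standardized.csv")

gt_records <- do.call(rbind, lapply(split(study$cells, study$cells$slide_id),
  function(cc) compute_ths(
    cell_annotations(cc$slide_id, "ground_truth", cc$x, cc$y, cc$grade),
    allow_fewer = TRUE)))

report <- build_report(
  ths_raw = ths_raw, ths_standardized = ths_std, ground_truth = gt_records,
  manifests = study$manifests,
  matched_fraction = matching$matched_fraction,
  confusion = matching$confusion
)
report$provenance <- list(seed = st$seed)
report_to_json(report, "results/report.json")

acc_gt <- report$accuracy$vs_ground_truth
acc_mean <- report$accuracy$vs_mean_annotators
cat(sprintf("accuracy vs ground truth: pooled %.1f%%, per annotator %.1f%%-%.1f%%\n",
            100 * acc_gt$pooled, 100 * min(acc_gt$per_rater),
            100 * max(acc_gt$per_rater)))
cat(sprintf("accuracy vs mean annotators' THS: pooled %.1f%%\n",
            100 * acc_mean$pooled))
k <- report$consensus$k
cat(sprintf("consensus 8/10: %.1f%%; 9/10: %.1f%% (standardized: %.1f%%)\n",
            100 * report$consensus$fraction[k == 8],
            100 * report$consensus$fraction[k == 9],
            100 * report$consensus$standardized_fraction[k == 9]))
co <- report$correlations
cat(sprintf("Spearman mean-annotators vs ground truth: %.2f\n",
            co$mean_annotators_vs_ground_truth))
cat(sprintf("Spearman with iron: mean-annotators %.2f, ground truth %.2f\n",
            co$mean_annotators_vs_iron, co$ground_truth_vs_iron))
cat(sprintf("Spearman with RBC %.2f, hemoglobin %.2f (acute markers)\n",
            co$mean_annotators_vs_rbc, co$mean_annotators_vs_hemoglobin))
cat("wrote results/report.json\n")
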
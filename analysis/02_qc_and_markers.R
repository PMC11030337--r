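#!/usr/bin/env Rscript

# Stage 2 — QC filtering, normalization and dual marker detection on the
# simulated atlas.
#
# QC thresholds are matched to the 1,000-gene desk-scale atlas (at least 100
# detected genes, at most 950, at most 1e5 total counts, at most 10%
# mitochondrial, doublet score at most 0.5). Markers are detected two ways:
# Wilcoxon rank-sum with a 0.25 natural-log fold-change floor, and the
# strict 60%-in / 10%-out detection-fraction specificity rule; a single best
# marker per cluster maximizes the detection margin.
#
# Reads:  data/atlas/
# Writes: results/qc_cells.tsv, results/markers_*.csv, results/best_markers.csv

library(scmodnet)
dir.create("results", showWarnings = FALSE)

counts <- read_counts_mtx("data/atlas")
metrics <- read_metrics("data/atlas/metrics.tsv")
labels <- read_labels("data/atlas/labels.tsv")

filt <- filter_cells(metrics, qc_thresholds(
  min_features = 100, max_features = 950, max_total_counts = 1e5,
  max_pct_mito = 10, doublet_score_threshold = 0.5))
write.table(filt$table, "results/qc_cells.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("QC retained %d / %d cells; exclusions: %s",
                length(filt$retained), nrow(metrics),
                paste(names(table(filt$table$reasons[!filt$table$retained])),
                      collapse = ", ")))

counts <- counts[filt$retained, ]
labels <- labels[labels$cell_id %in% filt$retained, ]
norm <- log_normalize(counts)

mk_rs <- ranksum_markers(norm, labels)
mk_sp <- specificity_markers(counts, labels)
best <- best_marker_per_cluster(list(mk_sp, mk_rs),
                                clusters = sort(unique(labels$cluster)))
write.csv(mk_rs, "results/markers_ranksum.csv", row.names = FALSE)
write.csv(mk_sp, "results/markers_specificity.csv", row.names = FALSE)
write.csv(best, "results/best_markers.csv", row.names = FALSE)

message(sprintf("rank-sum markers: %d records; specificity markers: %d; best per cluster:",
                nrow(mk_rs), nrow(mk_sp)))
print(best)
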
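#!/usr/bin/env Rscript

# Stage 4 — the two permutation procedures linking modules to clusters.
#
# (a) Association: per (cluster, module) one-sample t-statistics of the
#     module eigengene (cluster mean vs whole-atlas mean) referred to a
#     label-permutation null (1,000 permutations, two-sided), BH-corrected.
# (b) Connectivity sensitivity: each cluster is dropped in turn, total
#     intramodular connectivity (sum of |bicor|^2 within the module) is
#     recomputed, and the change is referred to a null of equally sized
#     uniformly random cell drops (1,000 permutations), BH-corrected.
#
# Reads:  data/atlas/, results/qc_cells.tsv, results/modules.tsv,
#         results/eigengenes.csv
# Writes: results/association.csv, results/connectivity.csv

library(scmodnet)

seed <- as.integer(Sys.getenv("ATLAS_SEED", "1"))
counts <- read_counts_mtx("data/atlas")
labels <- read_labels("data/atlas/labels.tsv")
qc <- read.table("results/qc_cells.tsv", sep = "\t", header = TRUE)
keep <- qc$cell_id[qc$retained]
labels <- labels[labels$cell_id %in% keep, ]

eig_tab <- read.csv("results/eigengenes.csv", check.names = FALSE)
eig <- as.matrix(eig_tab[, -1, drop = FALSE])
rownames(eig) <- eig_tab$cell_id

modules <- read.table("results/modules.tsv", sep = "\t", header = TRUE)
assignment <- setNames(modules$module, modules$gene)

norm <- log_normalize(counts[keep, ])
X <- as.matrix(norm[, modules$gene])

assoc <- permutation_association(eig, labels, n_perm = 1000, seed = seed + 1L)
write.csv(assoc, "results/association.csv", row.names = FALSE)
message(sprintf("association: %d / %d pairs at q < 0.05",
                sum(assoc$q_fdr < 0.05), nrow(assoc)))

conn <- connectivity_drop(X, assignment, labels, beta = 2,
                          n_perm = 1000, seed = seed + 2L)
write.csv(conn, "results/connectivity.csv", row.names = FALSE)
message(sprintf("connectivity: %d / %d pairs at q < 0.05",
                sum(conn$q_fdr < 0.05, na.rm = TRUE), nrow(conn)))

sig <- merge(assoc[assoc$q_fdr < 0.05, c("cluster", "module", "t", "q_fdr")],
             conn[, c("cluster", "module", "delta", "p_perm")],
             by = c("cluster", "module"))
message("cluster-module pairs flagged by the association test:")
print(sig[order(sig$module, sig$cluster), ], row.names = FALSE)
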
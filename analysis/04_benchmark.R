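#!/usr/bin/env Rscript
# Step 4 — benchmark the predicted network against the reference list and
# recompute the published summary arithmetic.
#
# The co-recruitment network from step 3 is compared with the half-recall
# reference interaction list from step 1: precision of predicted edges,
# random-network baseline, and recovery of the planted truth. The second
# block recomputes, with the same operations, the summary arithmetic of the
# published CBL/CBLB analysis from its printed counts.

library(recruitnet)

name <- "cbl_like"
summary_tab <- utils::read.delim(file.path("results/detection", name,
                                           "detection_summary.tsv"))
interactors <- summary_tab$protein[summary_tab$specific]
net <- read_edge_table(file.path("results/network", name,
                                 "network_edges.tsv"),
                       nodes = interactors)
ref <- read_reference(file.path("results/fixtures", name, "reference.tsv"),
                      alias_map = NULL)
truth_tab <- utils::read.delim(file.path("results/fixtures", name,
                                         "ground_truth.tsv"))

report <- benchmark_network(net, ref)
print(report)

# planted-truth recovery (reference covers ~half of the true edges, so the
# benchmark precision is bounded by that recall)
modules <- split(truth_tab$protein, truth_tab$module)
true_edges <- do.call(rbind, lapply(modules, function(m)
  t(utils::combn(as.character(m), 2))))
truth <- list(true_edges = true_edges)
cat(sprintf("edge recall of planted within-module pairs: %.3f (%d pairs)\n",
            edge_recall(net, truth), nrow(true_edges)))

outdir <- "results/benchmark"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(unclass(report), file.path(outdir, "benchmark.json"),
                     auto_unbox = TRUE, digits = NA)

# published-count arithmetic, recomputed
arith <- data.frame(
  quantity = c("cbl_network_p_threshold", "cbl_random_baseline",
               "cbl_cn_precision", "cbl_hc_precision",
               "cblb_cn_precision", "cblb_hc_precision",
               "cblb_first_neighbor_pct", "random_first_neighbor_pct",
               "ub_enrichment_ratio"),
  value = c(signif(bonferroni_threshold(5e-5, 98), 3),
            round2(random_baseline(302, 98)),
            round2(precision(62, 328)), round2(precision(37, 120)),
            round2(precision(7, 34)), round2(precision(2, 8)),
            round1(100 * 5 / 13),
            round1(expected_random_neighbor_rate(15, 98)),
            round1(enrichment_ratio(16.9, 3.57))))
utils::write.table(arith, file.path(outdir, "published_arithmetic.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(arith, row.names = FALSE)
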
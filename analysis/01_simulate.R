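#!/usr/bin/env Rscript
# Step 1 — generate the two synthetic bait experiments with known truth.
#
# Two time-resolved AP-MS experiments are simulated against matched
# wild-type controls: a CBL-like design (3 biological x 3 technical
# replicates) and a CBLB-like design (3 x 2), each over 5 stimulation
# conditions (unstimulated, 30, 120, 300, 600 s). 40 specific preys are
# planted in 4 kinetic modules of 10 on top of 200 shared contaminants;
# a reference interaction list covering half of the planted within-module
# pairs emulates an incomplete curated interaction database.

library(recruitnet)

seed <- 20160729L
outdir <- "results/fixtures"

experiments <- list(
  cbl_like = sim_config(n_bio = 3L, n_tech = 3L, seed = seed),
  cblb_like = sim_config(n_bio = 3L, n_tech = 2L, seed = seed + 1L)
)

for (name in names(experiments)) {
  sim <- simulate_experiment(experiments[[name]],
                             bait_name = toupper(name))
  ref <- truth_reference_list(sim$truth, recall = 0.5,
                              seed = experiments[[name]]$seed)
  paths <- write_fixture_files(sim, file.path(outdir, name), reference = ref)
  cat(sprintf(
    "%s: %d proteins x %d runs, %d planted preys in %d modules, %d/%d true edges in the reference\n",
    name, nrow(sim$intensities), ncol(sim$intensities),
    length(sim$truth$specific_ids),
    length(unique(stats::na.omit(sim$truth$module_of))),
    nrow(ref), nrow(sim$truth$true_edges)))
}
cat("fixtures written under", outdir, "\n")
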
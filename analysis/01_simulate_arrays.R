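#!/usr/bin/env Rscript
# Stage 1: generate the emulation inputs.
#
# Builds the default two-condition scenario -- 288 DSB hotspots on a
# three-chromosome desk-scale genome, 11 planted increased (4-5x), 6
# decreased (1/10-1/5), 1 de novo in condition A -- and writes the four
# simulated tiling arrays (two replicate induction pairs x two conditions),
# the hotspot intervals, the planted truth and the Southern-blot
# calibration pairs under results/inputs/.

suppressPackageStartupMessages(library(dsbquant))

seed <- 20131001
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- scenario_preset("paper-emulation", seed = seed)
truth <- scenario_truth(sc)

for (i in seq_len(nrow(sc$arrays))) {
  nm <- paste0(sc$arrays$condition[i], sc$arrays$pair[i])
  probes <- simulate_array_pair(sc, sc$arrays$condition[i], sc$arrays$pair[i])
  write_probe_table(probes, file.path(out, paste0("array_", nm, ".tsv")))
}

write_intervals_bed(truth, file.path(out, "hotspots.bed"))
write_intervals_bed(truth, file.path(out, "hotspots_truth.bed"),
                    extra = c("intensity", "effect", "true_breakage_B"))
utils::write.table(sc$southern, file.path(out, "southern_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
writeLines(c(sprintf("seed\t%d", seed),
             sprintf("refset\t%s", paste(sc$refset, collapse = ","))),
           file.path(out, "run_meta.tsv"))

cat("Simulated", nrow(sc$arrays), "arrays over",
    sum(genome_spec()$n_probes), "probes;", nrow(truth), "hotspots\n")
cat("Planted: ", sum(truth$class_truth == "increased"), "increased,",
    sum(truth$class_truth == "decreased"), "decreased,",
    sum(truth$class_truth == "de_novo"), "de novo\n")
cat("Hotspot intensity range:",
    paste(round(range(truth$intensity), 1), collapse = "-"),
    "fold over background\n")
cat("Inputs written under", out, "\n")
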
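#!/usr/bin/env Rscript
# Stage 1: generate a synthetic gene-trap screen under the default study
# conditions (30 true traps, 5 anti-oriented + 5 intergenic decoys, 10
# control-shared sites; triplicate reactions per arm, 5x PCR duplication,
# 0.5% substitution errors). Writes the reference, ground truth and
# FASTQ files under results/sim_run/.

suppressMessages(library(trapscreen))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

run <- simulate_screen(sim_config(seed = seed), "results/sim_run")

cat(sprintf("simulated screen (seed %d):\n", seed))
cat(sprintf("  genes: %d on %s\n", nrow(run$reference$annotation$genes),
            paste(names(run$reference$genome), collapse = ", ")))
print(table(run$events$event_class))
cat(sprintf("  reads: %d across %d FASTQ files\n", nrow(run$reads),
            length(list.files(file.path(run$dir, "fastq")))))
cat(sprintf("  outputs in %s\n", run$dir))
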
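#!/usr/bin/env Rscript
# Stage 4: apply the screen's filter ledger (minimum unique reads,
# read-stack orientation, negative-control subtraction, genic/fusion
# viability) and aggregate survivors into the final hit table with
# high-confidence tiers. Writes results/hits/.

suppressMessages(library(trapscreen))

sites <- read.delim("results/sites/site_calls.tsv",
                    stringsAsFactors = FALSE)
ann <- read_annotation("results/sim_run/annotation.gtf")
genome <- read_genome("results/sim_run/genome.fa")
ann$chroms <- union(ann$chroms, names(genome))
out_dir <- "results/hits"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ledger <- filter_ledger()
exp_sites <- sites[sites$arm == "experimental", ]
ctl_sites <- sites[sites$arm == "control", ]
fl <- apply_filter_ledger(exp_sites, ctl_sites, ann, ledger)
hits <- aggregate_hits(fl$survivors)

write.table(hits, file.path(out_dir, "hit_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fl$discards, file.path(out_dir, "discards.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fl$trace, file.path(out_dir, "filter_trace.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("filter ledger trace:\n")
print(fl$trace, row.names = FALSE)
cat(sprintf("\nfinal hit table: %d sites in %d genes ", nrow(hits),
            length(unique(hits$gene_id))))
cat(sprintf("(%d high-confidence genes with >=2 sites)\n",
            length(unique(hits$gene_id[hits$tier == "high_confidence"]))))
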
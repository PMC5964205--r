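# Independent oracles and small fixture builders used across the suite.

# ---- toy annotation built by hand (plus-strand 5-exon gene and a
# minus-strand 3-exon gene; first intron of gene B lies in the 5' UTR) ----
toy_annotation <- function() {
  exons <- rbind(
    data.frame(gene_id = "GA", transcript_id = "GA.t1", gene_name = "geneA",
               chrom = "chrT", strand = "+",
               start = c(100L, 350L, 500L, 700L, 900L),
               end = c(250L, 397L, 620L, 790L, 1000L),
               exon_rank = 1:5),
    data.frame(gene_id = "GB", transcript_id = "GB.t1", gene_name = "geneB",
               chrom = "chrT", strand = "-",
               start = c(2000L, 2300L, 2600L),
               end = c(2100L, 2450L, 2700L),
               exon_rank = 3:1))
  cds <- rbind(
    data.frame(gene_id = "GA", transcript_id = "GA.t1", chrom = "chrT",
               strand = "+",
               start = c(150L, 350L, 500L, 700L, 900L),
               end = c(250L, 397L, 620L, 790L, 960L),
               exon_rank = 1:5),
    # gene B: exon 1 (genomic [2600,2700)) is UTR-only; CDS begins in
    # exon 2 and spans into exon 3; total 150 + 60 = 210 nt
    data.frame(gene_id = "GB", transcript_id = "GB.t1", chrom = "chrT",
               strand = "-",
               start = c(2300L, 2040L), end = c(2450L, 2100L),
               exon_rank = 2:3))
  tx <- data.frame(
    transcript_id = c("GA.t1", "GB.t1"), gene_id = c("GA", "GB"),
    n_exons = c(5L, 3L), cds_nt = c(417L, 210L),
    protein_length_aa = c(138L, 69L), cds_complete = c(TRUE, TRUE))
  genes <- data.frame(
    gene_id = c("GA", "GB"), gene_name = c("geneA", "geneB"),
    chrom = "chrT", start = c(100L, 2000L), end = c(1000L, 2700L),
    strand = c("+", "-"))
  structure(list(genes = genes, transcripts = tx, exons = exons, cds = cds,
                 chroms = "chrT"), class = "trap_annotation")
}

# ---- brute-force flank mapper: full Hamming scan of every position on
# both strands, independent of the seed-and-extend implementation ----
brute_force_map <- function(flank, genome, max_mismatch = 2L) {
  cands <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") genome[[chrom]] else
        Biostrings::reverseComplement(genome[[chrom]])
      m <- Biostrings::matchPattern(Biostrings::DNAString(flank), subj,
                                    max.mismatch = max_mismatch)
      if (length(m) == 0) next
      for (k in seq_along(m)) {
        s <- Biostrings::start(m)[k]
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(flank),
                                          subj, starting.at = s)
        L <- nchar(flank)
        start0 <- if (strand == "+") s - 1L else length(subj) - (s - 1L) - L
        cands[[length(cands) + 1]] <- data.frame(
          chrom = chrom, strand = strand, start = start0, mm = mm)
      }
    }
  }
  if (length(cands) == 0) return(list(status = "unmapped"))
  cands <- do.call(rbind, cands)
  best <- cands[cands$mm == min(cands$mm), , drop = FALSE]
  if (nrow(best) > 1) return(list(status = "multimapped"))
  L <- nchar(flank)
  junction <- if (best$strand == "+") best$start else best$start + L - 1L
  list(status = "mapped", chrom = best$chrom, strand = best$strand,
       start = best$start, junction = junction, mm = best$mm)
}

# ---- pairwise overlap-closure (union-find) oracle for master blocks ----
overlap_closure_groups <- function(chrom, start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (chrom[i] == chrom[j] && start[i] < end[j] && start[j] < end[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# ---- fusion transcript construction + codon translation oracle ----
# frame-neutral 15-nt linker; starts CC so no chimeric codon across the
# splice junction can form a stop, and no frame of the linker itself stops
SPACER_15 <- "CCTGGAGGTTCAGGT"
HA_TAG <- "TACCCATACGATGTTCCAGATTACGCT"  # YPYDVPDYA

upstream_cds_seq <- function(ann, genome, transcript_id, intron_index) {
  cc <- ann$cds[ann$cds$transcript_id == transcript_id &
                ann$cds$exon_rank <= intron_index, , drop = FALSE]
  cc <- cc[order(cc$exon_rank), , drop = FALSE]
  segs <- vapply(seq_len(nrow(cc)), function(i) {
    s <- substr(as.character(genome[[cc$chrom[i]]]), cc$start[i] + 1,
                cc$end[i])
    if (cc$strand[i] == "-") as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))) else s
  }, character(1))
  paste0(segs, collapse = "")
}

translate_oracle <- function(dna) {
  dna <- substr(dna, 1, (nchar(dna) %/% 3) * 3)
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(dna),
                          if.fuzzy.codon = "solve")))
}

# Builds the spliced trap fusion mRNA for an insertion downstream of
# `intron_index` and returns its translation.
fusion_translation <- function(ann, genome, transcript_id, intron_index,
                               variant) {
  up <- upstream_cds_seq(ann, genome, transcript_id, intron_index)
  mrna <- paste0(up, SPACER_15, strrep("C", variant), HA_TAG, "GGTTAA")
  translate_oracle(mrna)
}

native_protein <- function(ann, genome, transcript_id) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  n_ex <- tx$n_exons
  full <- upstream_cds_seq(ann, genome, transcript_id, n_ex)
  sub("\\*$", "", translate_oracle(full))
}

# ---- convenience: default simulated screen, cached per test run ----
sim_run_cache <- new.env()
get_sim_run <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(sim_run_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("simrun_", seed))
    sim_run_cache[[key]] <- simulate_screen(sim_config(seed = seed), dir)
  }
  sim_run_cache[[key]]
}

get_pipeline_result <- function(seed = 101L) {
  key <- paste0("p", seed)
  if (is.null(sim_run_cache[[key]])) {
    run <- get_sim_run(seed)
    sim_run_cache[[key]] <- run_screen_pipeline(
      run, run$reference$genome, run$reference$annotation)
  }
  sim_run_cache[[key]]
}
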
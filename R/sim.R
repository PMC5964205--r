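# Synthetic nrLAM-PCR screen generator.
#
# Emulates the data structure of a Tol2 gene-trap biosensor screen:
# junction reads beginning with the transposon tag followed by a genomic
# flank of variable length (linear amplification), PCR duplicates that
# repeat a molecule's exact length, substitution errors, triplicate
# replicate reactions per arm, true intronic co-oriented insertions,
# anti-oriented and intergenic decoys, and false-positive sites shared
# with the negative-control arm.

TOL2_TAG <- "TTTGAGTACTTTTTACACCTCTG"

#' Simulation configuration
#'
#' Defaults define the reference screen conditions used throughout the
#' package's tests: a two-chromosome toy genome, ten multi-exon genes,
#' 30 true gene-trap insertions, 5 anti-oriented and 5 intergenic decoys,
#' and 10 sites seeded into both arms. Per site, 3-60 original molecules
#' with distinct flank lengths (geometric length distribution, mean 120
#' nt, minimum 25 nt), mean 5x PCR duplication, 0.005/nt substitution
#' error rate, and three replicate reactions each subsampling 80% of
#' molecules.
#'
#' @param seed integer; fully determines all outputs.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_genes number of genes embedded in the genome.
#' @param exon_range integer range of exons per gene.
#' @param intron_range integer range of intron lengths (bp).
#' @param protein_range integer range of protein lengths (aa).
#' @param n_true number of true gene-trap insertions (intronic,
#'   co-oriented, frame-matched).
#' @param n_anti number of anti-oriented intronic decoys.
#' @param n_intergenic number of intergenic decoys.
#' @param n_shared_control number of sites present in both arms.
#' @param mol_range integer range of unique molecules per site.
#' @param flank_min,flank_mean,flank_max flank length distribution (nt):
#'   geometric with the given mean, truncated to `[flank_min, flank_max]`.
#' @param dup_mean mean PCR duplicates per molecule (>= 1).
#' @param base_error_rate per-base substitution probability.
#' @param replicate_rate per-replicate molecule subsampling probability.
#' @param three_prime_bias exponent weighting insertion introns by
#'   relative 3' position (larger = stronger bias toward last introns,
#'   mimicking selection against nonsense-mediated decay).
#' @param tag transposon junction tag prepended to every read.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 100000L, chr2 = 50000L),
                       n_genes = 12L,
                       exon_range = c(4L, 8L),
                       intron_range = c(400L, 1200L),
                       protein_range = c(150L, 450L),
                       n_true = 30L,
                       n_anti = 5L,
                       n_intergenic = 5L,
                       n_shared_control = 10L,
                       mol_range = c(3L, 60L),
                       flank_min = 25L,
                       flank_mean = 120L,
                       flank_max = 250L,
                       dup_mean = 5,
                       base_error_rate = 0.005,
                       replicate_rate = 0.8,
                       three_prime_bias = 2,
                       tag = TOL2_TAG) {
  stopifnot(seed == as.integer(seed), all(chrom_lengths > 0),
            n_genes >= 0, n_true >= 0, n_anti >= 0, n_intergenic >= 0,
            n_shared_control >= 0, flank_min >= 20, dup_mean >= 1,
            replicate_rate > 0, replicate_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste0,
                    collapse = "")
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random composition of `total` into `k` parts, each >= minimum.
random_parts <- function(total, k, minimum) {
  spare <- total - k * minimum
  stopifnot(spare >= 0)
  if (k == 1) return(total)
  cuts <- sort(sample(0:spare, k - 1, replace = TRUE))
  minimum + diff(c(0, cuts, spare))
}

# One gene in transcript space: returns exon/intron layout plus sequence.
build_gene <- function(cfg) {
  n_exons <- sample(cfg$exon_range[1]:cfg$exon_range[2], 1)
  n_res <- sample(cfg$protein_range[1]:cfg$protein_range[2], 1)
  cds_nt <- 3L * (n_res + 1L)                    # incl. stop codon
  cds_seq <- paste0(c("ATG", sample(SENSE_CODONS, n_res - 1, replace = TRUE),
                      sample(STOP_CODONS, 1)), collapse = "")
  utr5 <- 30L; utr3 <- 30L
  cds_parts <- random_parts(cds_nt, n_exons, 30L)
  exon_len <- cds_parts
  exon_len[1] <- exon_len[1] + utr5
  exon_len[n_exons] <- exon_len[n_exons] + utr3
  intron_len <- sample(cfg$intron_range[1]:cfg$intron_range[2],
                       n_exons - 1, replace = TRUE)
  # transcript-space coordinates (0-based half-open)
  exon_start <- integer(n_exons); pos <- 0L
  gene_seq <- character(2 * n_exons - 1)
  cds_off <- cumsum(c(0L, cds_parts))
  for (i in seq_len(n_exons)) {
    exon_start[i] <- pos
    cds_chunk <- substr(cds_seq, cds_off[i] + 1, cds_off[i + 1])
    exon_seq <- cds_chunk
    if (i == 1) exon_seq <- paste0(random_dna(utr5), exon_seq)
    if (i == n_exons) exon_seq <- paste0(exon_seq, random_dna(utr3))
    gene_seq[2 * i - 1] <- exon_seq
    pos <- pos + exon_len[i]
    if (i < n_exons) {
      iseq <- random_dna(intron_len[i])
      substr(iseq, 1, 2) <- "GT"; substr(iseq, intron_len[i] - 1,
                                         intron_len[i]) <- "AG"
      gene_seq[2 * i] <- iseq
      pos <- pos + intron_len[i]
    }
  }
  list(n_exons = n_exons, exon_start = exon_start, exon_len = exon_len,
       cds_parts = cds_parts, utr5 = utr5, utr3 = utr3,
       length = pos, seq = paste0(gene_seq, collapse = ""),
       cds_seq = cds_seq, protein_length_aa = n_res)
}

#' Generate a toy reference genome and annotation
#'
#' Embeds `n_genes` multi-exon protein-coding genes (complete ATG..stop
#' CDS, GT..AG intron boundaries) on both strands of a random genome.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `annotation`
#'   (`trap_annotation`-shaped list built directly from the truth),
#'   and `manifest` (per-gene structure table incl. CDS sequence).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  chroms <- lapply(config$chrom_lengths, random_dna)
  genes <- if (config$n_genes > 0)
    lapply(seq_len(config$n_genes), function(i) build_gene(config)) else
    list()

  # place genes sequentially with random gaps, margin from chromosome ends
  margin <- 2000L; gap_range <- c(1200L, 3000L)
  placements <- list(); ci <- 1L
  cursor <- margin
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    placed <- FALSE
    while (ci <= length(chroms)) {
      cursor <- cursor + sample(gap_range[1]:gap_range[2], 1)
      if (cursor + g$length + margin <= config$chrom_lengths[ci]) {
        placements[[i]] <- list(chrom = names(config$chrom_lengths)[ci],
                                start = cursor)
        cursor <- cursor + g$length
        placed <- TRUE
        break
      }
      ci <- ci + 1L; cursor <- margin
    }
    if (!placed) stop("gene placement failed; use larger chromosomes")
  }

  exon_rows <- list(); cds_rows <- list(); gene_rows <- list()
  manifest <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]; pl <- placements[[i]]
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("GENE%03d", i)
    seq_fwd <- if (strand == "+") g$seq else revcomp_chr(g$seq)
    ch <- chroms[[pl$chrom]]
    substr(ch, pl$start + 1, pl$start + g$length) <- seq_fwd
    chroms[[pl$chrom]] <- ch
    # transcript-space [a,b) -> genomic
    t2g <- function(a, b) {
      if (strand == "+") c(pl$start + a, pl$start + b) else
        c(pl$start + g$length - b, pl$start + g$length - a)
    }
    for (e in seq_len(g$n_exons)) {
      a <- g$exon_start[e]; b <- a + g$exon_len[e]
      ge <- t2g(a, b)
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".t1"),
        gene_name = paste0("gene", i), chrom = pl$chrom, strand = strand,
        start = ge[1], end = ge[2], exon_rank = e, stringsAsFactors = FALSE)
      ca <- a + if (e == 1) g$utr5 else 0L
      cb <- ca + g$cds_parts[e]
      gc <- t2g(ca, cb)
      cds_rows[[length(cds_rows) + 1]] <- data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".t1"),
        chrom = pl$chrom, strand = strand, start = gc[1], end = gc[2],
        exon_rank = e, stringsAsFactors = FALSE)
    }
    gspan <- t2g(0L, g$length)
    gene_rows[[length(gene_rows) + 1]] <- data.frame(
      gene_id = gid, gene_name = paste0("gene", i), chrom = pl$chrom,
      start = gspan[1], end = gspan[2], strand = strand,
      stringsAsFactors = FALSE)
    manifest[[length(manifest) + 1]] <- data.frame(
      gene_id = gid, gene_name = paste0("gene", i), chrom = pl$chrom,
      strand = strand, start = gspan[1], end = gspan[2],
      n_exons = g$n_exons, cds_nt = nchar(g$cds_seq),
      protein_length_aa = g$protein_length_aa, cds_seq = g$cds_seq,
      stringsAsFactors = FALSE)
  }

  exons <- if (length(exon_rows)) do.call(rbind, exon_rows) else data.frame()
  cds <- if (length(cds_rows)) do.call(rbind, cds_rows) else data.frame()
  genes_df <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(0), gene_name = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  tx <- if (nrow(genes_df) > 0) do.call(rbind, lapply(
    split(cds, cds$transcript_id), function(cc) {
      nt <- sum(cc$end - cc$start)
      data.frame(transcript_id = cc$transcript_id[1],
                 gene_id = cc$gene_id[1],
                 n_exons = sum(exons$transcript_id == cc$transcript_id[1]),
                 cds_nt = nt, protein_length_aa = nt %/% 3L - 1L,
                 cds_complete = nt %% 3 == 0, stringsAsFactors = FALSE)
    })) else
    data.frame(transcript_id = character(0), gene_id = character(0),
               n_exons = integer(0), cds_nt = integer(0),
               protein_length_aa = integer(0), cds_complete = logical(0))
  rownames(tx) <- NULL
  annotation <- structure(list(genes = genes_df, transcripts = tx,
                               exons = exons, cds = cds,
                               chroms = names(config$chrom_lengths)),
                          class = "trap_annotation")
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  names(genome) <- names(config$chrom_lengths)
  list(genome = genome, annotation = annotation,
       manifest = if (length(manifest)) do.call(rbind, manifest) else
         data.frame())
}

#' Write a reference to FASTA + GTF on disk
#'
#' @param reference result of [generate_reference()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (`fasta`, `gtf`, `manifest`).
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(reference$genome, fasta)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(reference$annotation, gtf)
  man <- file.path(dir, "gene_manifest.tsv")
  write.table(reference$manifest, man, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(fasta = fasta, gtf = gtf, manifest = man)
}

# GTF 2.2 writer for the annotation structure (1-based inclusive on write).
write_gtf <- function(ann, path) {
  rows <- character(0)
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\ttrapscreen\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  }
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    ga <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
    rows <- c(rows, fmt(g$chrom, "gene", g$start, g$end, g$strand, ga))
    tx <- ann$transcripts[ann$transcripts$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(tx))) {
      t <- tx[j, ]
      ta <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                    g$gene_id, t$transcript_id, g$gene_name)
      e <- ann$exons[ann$exons$transcript_id == t$transcript_id, ]
      rows <- c(rows, fmt(g$chrom, "transcript", min(e$start), max(e$end),
                          g$strand, ta))
      for (k in order(e$exon_rank)) {
        rows <- c(rows, fmt(g$chrom, "exon", e$start[k], e$end[k], g$strand,
                            sprintf('%s exon_number "%d";', ta,
                                    e$exon_rank[k])))
      }
      cc <- ann$cds[ann$cds$transcript_id == t$transcript_id, ]
      for (k in order(cc$exon_rank)) {
        rows <- c(rows, fmt(g$chrom, "CDS", cc$start[k], cc$end[k], g$strand,
                            sprintf('%s exon_number "%d";', ta,
                                    cc$exon_rank[k])))
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}

# Intron table (genomic coordinates + transcription-order index + phase).
intron_table <- function(ann) {
  out <- list()
  for (t in unique(ann$exons$transcript_id)) {
    e <- ann$exons[ann$exons$transcript_id == t, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    strand <- e$strand[1]
    for (k in seq_len(nrow(e) - 1)) {
      idx <- if (strand == "+") e$exon_rank[k] else e$exon_rank[k + 1]
      up <- upstream_cds_nt(list(cds = ann$cds), t, idx)
      out[[length(out) + 1]] <- data.frame(
        gene_id = e$gene_id[1], transcript_id = t, chrom = e$chrom[1],
        strand = strand, intron_index = idx,
        start = e$end[k], end = e$start[k + 1],
        n_introns = nrow(e) - 1, upstream_cds_nt = up,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Sample ground-truth insertion events
#'
#' Draws the configured numbers of true traps (intronic, co-oriented,
#' frame-matched, 3'-biased), anti-oriented intronic decoys, intergenic
#' decoys, and control-shared sites. Junctions are mutually separated by
#' more than twice the maximum flank length so that no two events can
#' share a master block.
#'
#' @param reference result of [generate_reference()].
#' @param config the [sim_config()] used to generate it.
#' @return data.frame of events (`event_id`, `chrom`, `pos` 0-based
#'   junction, `orientation`, `variant`, `host_gene`, `intron_index`,
#'   `arm`, `event_class`).
#' @export
sample_insertions <- function(reference, config) {
  set.seed(config$seed + 1L)
  ann <- reference$annotation
  introns <- intron_table(ann)
  sep <- 2L * config$flank_max + 20L
  taken <- list()
  ok_pos <- function(chrom, pos) {
    tk <- taken[[chrom]]
    is.null(tk) || all(abs(tk - pos) >= sep)
  }
  claim <- function(chrom, pos) taken[[chrom]] <<- c(taken[[chrom]], pos)

  viable_introns <- introns[introns$upstream_cds_nt >= 3, , drop = FALSE]
  n_viable_needed <- config$n_true + config$n_shared_control
  if (n_viable_needed > 0 &&
      (is.null(viable_introns) || nrow(viable_introns) == 0)) {
    stop("requested insertions exceed available introns")
  }

  draw_intronic <- function(class, arm, co_oriented) {
    w <- (viable_introns$intron_index / viable_introns$n_introns) ^
      config$three_prime_bias
    for (try in 1:500) {
      # the 3' bias concentrates draws on last introns; once those fill
      # up (separation constraint), fall back to uniform intron choice
      iv <- viable_introns[sample(nrow(viable_introns), 1,
                                  prob = if (try <= 100) w else NULL), ]
      if (iv$end - iv$start < 20L) next
      pos <- sample((iv$start + 5L):(iv$end - 6L), 1)
      if (!ok_pos(iv$chrom, pos)) next
      claim(iv$chrom, pos)
      ori <- if (co_oriented) iv$strand else setdiff(c("+", "-"), iv$strand)
      phase <- iv$upstream_cds_nt %% 3L
      variant <- if (co_oriented) (3L - phase) %% 3L else sample(0:2, 1)
      return(data.frame(chrom = iv$chrom, pos = pos, orientation = ori,
                        variant = variant, host_gene = iv$gene_id,
                        intron_index = iv$intron_index, arm = arm,
                        event_class = class, stringsAsFactors = FALSE))
    }
    stop("could not place ", class, " event; too many insertions for ",
         "the available intron space")
  }
  draw_intergenic <- function(arm) {
    for (try in 1:500) {
      chrom <- sample(names(config$chrom_lengths), 1)
      L <- config$chrom_lengths[[chrom]]
      pos <- sample(config$flank_max:(L - config$flank_max), 1)
      g <- ann$genes
      ingene <- nrow(g) > 0 && any(g$chrom == chrom & g$start - 50 <= pos &
                                   g$end + 50 > pos)
      if (ingene || !ok_pos(chrom, pos)) next
      claim(chrom, pos)
      return(data.frame(chrom = chrom, pos = pos,
                        orientation = sample(c("+", "-"), 1),
                        variant = sample(0:2, 1), host_gene = NA_character_,
                        intron_index = NA_integer_, arm = arm,
                        event_class = "intergenic", stringsAsFactors = FALSE))
    }
    stop("could not place intergenic event")
  }

  ev <- list()
  for (i in seq_len(config$n_true))
    ev[[length(ev) + 1]] <- draw_intronic("true_trap", "experimental", TRUE)
  for (i in seq_len(config$n_anti))
    ev[[length(ev) + 1]] <- draw_intronic("anti_oriented", "experimental",
                                          FALSE)
  for (i in seq_len(config$n_intergenic))
    ev[[length(ev) + 1]] <- draw_intergenic("experimental")
  for (i in seq_len(config$n_shared_control))
    ev[[length(ev) + 1]] <- draw_intronic("control_shared", "both", TRUE)
  if (length(ev) == 0) {
    return(data.frame(event_id = character(0), chrom = character(0),
                      pos = integer(0), orientation = character(0),
                      variant = integer(0), host_gene = character(0),
                      intron_index = integer(0), arm = character(0),
                      event_class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  out <- cbind(event_id = sprintf("EV%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

mutate_bases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    pos <- sample(lens[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

#' Simulate nrLAM-PCR junction reads
#'
#' Each read is the transposon tag followed by a genomic flank starting
#' at the event's junction base and read in the orientation of the
#' splice-acceptor cassette (a co-oriented trap yields flanks on the host
#' gene's strand). Unique molecules of one site carry distinct flank
#' lengths; PCR duplicates repeat a molecule's exact length; replicates
#' A/B/C independently subsample molecules; substitution errors are
#' applied after read assembly.
#'
#' @param reference result of [generate_reference()].
#' @param events result of [sample_insertions()].
#' @param config the [sim_config()].
#' @return list with `reads` (per-read truth data.frame: `read_id`,
#'   `seq`, `arm`, `replicate`, `event_id`, `chrom`, `junction`,
#'   `orientation`, `flank_length`) and `molecules` (per-molecule truth).
#' @export
simulate_reads <- function(reference, events, config) {
  chrom_chr <- as.character(reference$genome)
  arms_of <- function(a) switch(a, experimental = "experimental",
                                control = "control",
                                both = c("experimental", "control"))
  p_geom <- 1 / (config$flank_mean - config$flank_min + 1)
  len_domain <- config$flank_min:config$flank_max
  len_w <- (1 - p_geom) ^ (len_domain - config$flank_min)

  # pass 1 (structural draws): molecules, lengths and replicate
  # subsampling. Drawn before any amplification/error randomness so that
  # the molecule structure is invariant under the PCR duplication factor
  # and the base error rate.
  set.seed(config$seed + 2L)
  mols <- list(); kept <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    chrom_len <- nchar(chrom_chr[[e$chrom]])
    avail <- if (e$orientation == "+") chrom_len - e$pos else e$pos + 1L
    dom_ok <- len_domain <= avail
    for (arm in arms_of(e$arm)) {
      n_mol <- sample(config$mol_range[1]:config$mol_range[2], 1)
      n_mol <- min(n_mol, sum(dom_ok))
      lens <- sample(len_domain[dom_ok], n_mol, prob = len_w[dom_ok])
      mols[[length(mols) + 1]] <- data.frame(
        event_id = e$event_id, arm = arm, molecule = seq_len(n_mol),
        flank_length = lens, stringsAsFactors = FALSE)
      for (rep_id in c("A", "B", "C")) {
        keep <- which(rbinom(n_mol, 1, config$replicate_rate) == 1)
        if (length(keep) == 0) next
        kept[[length(kept) + 1]] <- list(event = i, arm = arm,
                                         rep_id = rep_id, keep = keep,
                                         lens = lens[keep])
      }
    }
  }

  # pass 2 (amplification + errors): PCR duplicate counts and
  # substitution errors per retained molecule
  set.seed(config$seed + 3L)
  reads <- list()
  for (k in kept) {
    e <- events[k$event, ]
    chrom_seq <- chrom_chr[[e$chrom]]
    dup <- 1L + rpois(length(k$keep), config$dup_mean - 1)
    mol_ord <- rep(seq_along(k$keep), dup)
    lens <- k$lens[mol_ord]
    flanks <- if (e$orientation == "+") {
      substring(chrom_seq, e$pos + 1, e$pos + lens)
    } else {
      revcomp_chr(substring(chrom_seq, e$pos - lens + 2, e$pos + 1))
    }
    seqs <- mutate_bases(paste0(config$tag, flanks),
                         config$base_error_rate)
    ids <- sprintf("%s:%s:%s:m%d:d%d", e$event_id, k$arm, k$rep_id,
                   k$keep[mol_ord], unlist(lapply(dup, seq_len)))
    reads[[length(reads) + 1]] <- data.frame(
      read_id = ids, seq = seqs, arm = k$arm, replicate = k$rep_id,
      event_id = e$event_id, chrom = e$chrom, junction = e$pos,
      orientation = e$orientation, flank_length = lens,
      stringsAsFactors = FALSE)
  }
  reads_df <- if (length(reads)) do.call(rbind, reads) else
    data.frame(read_id = character(0), seq = character(0),
               arm = character(0), replicate = character(0),
               event_id = character(0), chrom = character(0),
               junction = integer(0), orientation = character(0),
               flank_length = integer(0), stringsAsFactors = FALSE)
  rownames(reads_df) <- NULL
  list(reads = reads_df,
       molecules = if (length(mols)) do.call(rbind, mols) else data.frame())
}

#' Simulate a complete screen run to disk
#'
#' Writes the reference (FASTA + GTF + gene manifest), the ground-truth
#' event and per-read tables, per arm x replicate FASTQ files, and a JSON
#' run manifest recording the seed and record counts. The output
#' directory is directly consumable by [run_screen_pipeline()].
#'
#' @param config a [sim_config()].
#' @param dir output run directory.
#' @return list with `dir`, file paths, and the in-memory `reference`,
#'   `events` and `reads` objects.
#' @export
simulate_screen <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reference <- generate_reference(config)
  ref_files <- write_reference(reference, dir)
  events <- sample_insertions(reference, config)
  write.table(events, file.path(dir, "truth_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sim <- simulate_reads(reference, events, config)
  fastq_dir <- file.path(dir, "fastq")
  dir.create(fastq_dir, showWarnings = FALSE)
  manifest_rows <- list()
  for (arm in c("experimental", "control")) {
    for (rep_id in c("A", "B", "C")) {
      sub <- sim$reads[sim$reads$arm == arm & sim$reads$replicate == rep_id, ]
      f <- file.path(fastq_dir, sprintf("%s_%s.fastq", arm, rep_id))
      write_fastq(sub$read_id, sub$seq, f)
      manifest_rows[[length(manifest_rows) + 1]] <- list(
        file = f, arm = arm, replicate = rep_id, n_reads = nrow(sub))
    }
  }
  truth_reads <- sim$reads[, setdiff(names(sim$reads), "seq")]
  write.table(truth_reads, file.path(dir, "truth_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(seed = config$seed,
                   tag = config$tag,
                   genome = ref_files$fasta, annotation = ref_files$gtf,
                   fastq = manifest_rows,
                   n_events = nrow(events),
                   n_reads = nrow(sim$reads))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(dir = dir, reference = reference, events = events,
       reads = sim$reads, molecules = sim$molecules,
       fasta = ref_files$fasta, gtf = ref_files$gtf,
       gene_manifest = ref_files$manifest,
       manifest = file.path(dir, "run_manifest.json"))
}
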
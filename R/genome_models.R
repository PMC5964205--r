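# Gene-structure models and splice-acceptor fusion-frame prediction.
#
# Coordinates are 0-based half-open internally (BED convention); GTF input
# is converted on read and all user-facing reports print 1-based positions.

#' Read a reference genome from FASTA
#'
#' @param path path to a FASTA file.
#' @return named `DNAStringSet`, one entry per chromosome, sequences
#'   uppercased and names truncated at the first whitespace.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  if (file.info(path)$size == 0) {
    return(Biostrings::DNAStringSet())
  }
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  names(ss) <- sub("\\s.*$", "", names(ss))
  bad <- names(ss)[!nzchar(names(ss))]
  if (length(bad)) stop("malformed FASTA: record with empty name")
  Biostrings::DNAStringSet(toupper(as.character(ss)))
}

#' Read gene annotation from GTF
#'
#' Builds per-gene transcript/exon/CDS structure. Exons are ranked in
#' transcription order (ascending coordinates on `+`, descending on `-`).
#' Transcripts whose total CDS length is not a multiple of 3 are flagged
#' incomplete and excluded from fusion prediction.
#'
#' @param path path to a GTF file with gene/transcript/exon/CDS features
#'   carrying `gene_id` and `transcript_id` attributes.
#' @return object of class `trap_annotation`: a list with data frames
#'   `genes`, `transcripts`, `exons`, `cds` (0-based half-open coordinates).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation GTF not found: ", path)
  empty <- structure(list(
    genes = data.frame(gene_id = character(0), gene_name = character(0),
                       chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0)),
    transcripts = data.frame(transcript_id = character(0),
                             gene_id = character(0), n_exons = integer(0),
                             cds_nt = integer(0),
                             protein_length_aa = integer(0),
                             cds_complete = logical(0)),
    exons = data.frame(), cds = data.frame()), class = "trap_annotation")
  lines <- readLines(path)
  feat <- !grepl("^#", lines) & nzchar(lines)
  if (!any(feat)) return(empty)
  needs_gene <- grepl("\t(exon|CDS|transcript|gene)\t", lines)
  missing_gid <- which(feat & needs_gene & !grepl("gene_id", lines))
  if (length(missing_gid)) {
    stop("GTF record missing gene_id attribute at line ", missing_gid[1])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) return(empty)
  md <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    stringsAsFactors = FALSE)
  df$transcript_id <- if ("transcript_id" %in% names(md))
    as.character(md$transcript_id) else NA_character_
  df$gene_name <- if ("gene_name" %in% names(md))
    as.character(md$gene_name) else df$gene_id

  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(ex) == 0) return(empty)

  # per-transcript exon ranking in transcription order
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  ex_list <- split(ex, ex$transcript_id)
  ex <- do.call(rbind, lapply(ex_list, function(e) {
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("overlapping exons within transcript ", e$transcript_id[1])
    }
    e$exon_rank <- if (e$strand[1] == "-") rev(seq_len(nrow(e))) else
      seq_len(nrow(e))
    e
  }))
  rownames(ex) <- NULL

  # attach each CDS segment to its exon (containment)
  if (nrow(cds) > 0) {
    cds$exon_rank <- NA_integer_
    for (i in seq_len(nrow(cds))) {
      m <- which(ex$transcript_id == cds$transcript_id[i] &
                 ex$start <= cds$start[i] & ex$end >= cds$end[i])
      if (length(m) == 1) cds$exon_rank[i] <- ex$exon_rank[m]
    }
  }

  cds_by_tx <- if (nrow(cds)) split(cds, cds$transcript_id) else list()
  tx_ids <- unique(ex$transcript_id)
  tx <- do.call(rbind, lapply(tx_ids, function(t) {
    e <- ex[ex$transcript_id == t, ]
    cc <- cds_by_tx[[t]]
    cds_nt <- if (is.null(cc)) 0L else sum(cc$end - cc$start)
    complete <- cds_nt > 0 && cds_nt %% 3 == 0
    data.frame(transcript_id = t, gene_id = e$gene_id[1],
               n_exons = nrow(e), cds_nt = cds_nt,
               protein_length_aa = if (complete) cds_nt %/% 3L - 1L else
                 NA_integer_,
               cds_complete = complete, stringsAsFactors = FALSE)
  }))

  gn_ids <- unique(df$gene_id[df$type %in% c("gene", "exon")])
  genes <- do.call(rbind, lapply(gn_ids, function(g) {
    sub <- df[df$gene_id == g & df$type %in% c("gene", "exon"), ]
    data.frame(gene_id = g, gene_name = sub$gene_name[1],
               chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end), strand = sub$strand[1],
               stringsAsFactors = FALSE)
  }))
  structure(list(genes = genes, transcripts = tx, exons = ex,
                 cds = cds[!is.na(cds$exon_rank) | nrow(cds) == 0, ,
                           drop = FALSE],
                 chroms = unique(df$chrom)),
            class = "trap_annotation")
}

# CDS nucleotides in exons ranked 1..k (transcription order) of a transcript.
upstream_cds_nt <- function(ann, transcript_id, k) {
  cc <- ann$cds[ann$cds$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(cc) == 0) return(0L)
  sum(cc$end[cc$exon_rank <= k] - cc$start[cc$exon_rank <= k])
}

#' Coding phase of an intron
#'
#' Phase is the cumulative count of coding nucleotides in exons upstream
#' of the intron, modulo 3. It is undefined (`NA`) when no coding
#' nucleotide lies upstream, i.e. the intron precedes the CDS start.
#'
#' @param ann a `trap_annotation`.
#' @param transcript_id transcript identifier.
#' @param intron_index 1-based index in transcription order;
#'   intron `i` separates exon `i` from exon `i + 1`.
#' @return integer phase in 0:2, or `NA` for a pre-CDS intron.
#' @export
intron_phase <- function(ann, transcript_id, intron_index) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  if (nrow(tx) == 0) stop("unknown transcript: ", transcript_id)
  if (intron_index < 1 || intron_index > tx$n_exons - 1) {
    stop("intron_index ", intron_index, " out of range for transcript ",
         transcript_id, " (", tx$n_exons - 1, " introns)")
  }
  up <- upstream_cds_nt(ann, transcript_id, intron_index)
  if (up == 0L) return(NA_integer_)
  as.integer(up %% 3L)
}

# Fusion transcript for a gene: longest complete CDS, ties by transcript_id.
fusion_transcript <- function(ann, gene_id, transcript_override = NULL) {
  tx <- ann$transcripts[ann$transcripts$gene_id == gene_id, , drop = FALSE]
  if (!is.null(transcript_override)) {
    tx <- tx[tx$transcript_id == transcript_override, , drop = FALSE]
    if (nrow(tx) == 0) stop("transcript override not in gene: ",
                            transcript_override)
    return(tx)
  }
  tx <- tx[tx$cds_complete, , drop = FALSE]
  if (nrow(tx) == 0) return(NULL)
  tx <- tx[order(-tx$cds_nt, tx$transcript_id), , drop = FALSE]
  tx[1, , drop = FALSE]
}

#' Locate an insertion site within the gene annotation
#'
#' Resolves a single-base junction coordinate against gene models. When
#' genes overlap on opposite strands the gene whose strand matches the
#' insertion orientation is preferred; an antisense-only overlap is
#' reported with `orientation_match = FALSE`.
#'
#' @param ann a `trap_annotation`.
#' @param chrom chromosome name.
#' @param pos 0-based junction coordinate.
#' @param orientation `"+"` or `"-"`: strand of the splice-acceptor
#'   cassette.
#' @param transcript_override optional transcript_id forcing the fusion
#'   transcript choice.
#' @return list with `status` (one of `"intergenic"`, `"exonic"`,
#'   `"intronic"`, `"outside_transcript"`, `"no_cds"`), and for genic
#'   sites `gene_id`, `gene_name`, `gene_strand`, `orientation_match`,
#'   `transcript_id`, `intron_index`, `upstream_cds_nt`,
#'   `protein_length_aa`.
#' @export
locate_insertion <- function(ann, chrom, pos, orientation,
                             transcript_override = NULL) {
  known <- ann$chroms %||% unique(ann$genes$chrom)
  if (length(known) > 0 && !chrom %in% known) {
    stop("chromosome absent from annotation: ", chrom)
  }
  g <- ann$genes[ann$genes$chrom == chrom & ann$genes$start <= pos &
                 ann$genes$end > pos, , drop = FALSE]
  if (nrow(g) == 0) return(list(status = "intergenic"))
  hit <- g[g$strand == orientation, , drop = FALSE]
  orientation_match <- nrow(hit) > 0
  if (!orientation_match) hit <- g
  gene <- hit[1, ]

  tx <- fusion_transcript(ann, gene$gene_id, transcript_override)
  base <- list(gene_id = gene$gene_id, gene_name = gene$gene_name,
               gene_strand = gene$strand,
               orientation_match = orientation_match)
  if (is.null(tx)) return(c(list(status = "no_cds"), base))

  e <- ann$exons[ann$exons$transcript_id == tx$transcript_id, , drop = FALSE]
  e <- e[order(e$exon_rank), , drop = FALSE]
  if (pos < min(e$start) || pos >= max(e$end)) {
    return(c(list(status = "outside_transcript",
                  transcript_id = tx$transcript_id), base))
  }
  in_exon <- any(e$start <= pos & e$end > pos)
  if (in_exon) {
    return(c(list(status = "exonic", transcript_id = tx$transcript_id), base))
  }
  # genomic-order exons; intron between genomic neighbours
  eg <- e[order(e$start), , drop = FALSE]
  k_genomic <- max(which(eg$end <= pos))
  # intron index in transcription order = rank of the upstream-side exon
  upstream_rank <- if (gene$strand == "+") eg$exon_rank[k_genomic] else
    eg$exon_rank[k_genomic + 1]
  up <- upstream_cds_nt(ann, tx$transcript_id, upstream_rank)
  c(list(status = "intronic", transcript_id = tx$transcript_id,
         intron_index = as.integer(upstream_rank),
         upstream_cds_nt = as.integer(up),
         protein_length_aa = tx$protein_length_aa), base)
}

#' Predict gene-trap fusion viability and truncation
#'
#' A splice-acceptor trap produces a fusion protein only when the
#' insertion is intronic, co-directional with transcription, and at least
#' one complete codon of coding sequence lies upstream. The reporter
#' cassette exists in three frame variants carrying 0, 1 or 2 C bases of
#' padding; the variant complementing the intron phase
#' (`(3 - phase) mod 3`) restores the reading frame across the splice.
#'
#' The retained N-terminal fragment is `floor(upstream_cds_nt / 3)`
#' residues: a partial codon interrupted by the splice junction encodes a
#' chimeric residue and is not counted.
#'
#' @param context result of [locate_insertion()].
#' @param variant optional frame variant in `0:2`; when supplied (strict
#'   mode) viability additionally requires this variant to match the
#'   intron phase. Default `NULL` (all-variant mode) reports the single
#'   complementing variant.
#' @return list with `viable`, `matching_variants` (integer vector),
#'   `truncation_aa`, `intron_index`, `upstream_cds_nt`.
#' @export
predict_fusion <- function(context, variant = NULL) {
  if (is.null(context$status)) stop("undefined insertion context")
  if (!is.null(variant) && !variant %in% 0:2) stop("variant must be 0, 1 or 2")
  non_viable <- list(viable = FALSE, matching_variants = integer(0),
                     truncation_aa = 0L,
                     intron_index = context$intron_index %||% NA_integer_,
                     upstream_cds_nt = context$upstream_cds_nt %||% 0L)
  if (context$status != "intronic") return(non_viable)
  up <- context$upstream_cds_nt
  if (is.null(up) || up < 3L) return(non_viable)  # pre-CDS or <1 codon
  phase <- up %% 3L
  matching <- as.integer((3L - phase) %% 3L)
  viable <- isTRUE(context$orientation_match) &&
    (is.null(variant) || variant == matching)
  list(viable = viable, matching_variants = matching,
       truncation_aa = as.integer(up %/% 3L),
       intron_index = context$intron_index,
       upstream_cds_nt = as.integer(up))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
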
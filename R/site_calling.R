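# Cross-sample master blocks, unique-length PCR deduplication, and
# per-site replicate counting.
#
# Master blocks are maximal genomic intervals covering every set of
# mutually overlapping alignments across all sequenced samples jointly;
# they are the unit at which integration sites are counted and compared
# between the experimental and control arms. Linear amplification makes
# every original molecule of a site carry a distinct fragment length, so
# PCR duplicates collapse by counting distinct flank lengths.

#' Build cross-sample master blocks
#'
#' Single-linkage merge of overlapping alignment intervals pooled over
#' every sample (both arms, all replicates). Blocks receive deterministic
#' ids ordered by (chrom, start).
#'
#' @param alignments data.frame of alignments (columns `chrom`, `start`,
#'   `end`, 0-based half-open; any sample columns are carried).
#' @return list with `blocks` (data.frame `block_id`, `chrom`, `start`,
#'   `end`, `n_members`) and `alignments` (input plus `block_id`).
#' @export
build_master_blocks <- function(alignments) {
  if (nrow(alignments) == 0) {
    return(list(blocks = data.frame(block_id = character(0),
                                    chrom = character(0), start = integer(0),
                                    end = integer(0), n_members = integer(0)),
                alignments = cbind(alignments, block_id = character(0))))
  }
  gr <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(start = alignments$start + 1L, end = alignments$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L,
                                  ignore.strand = TRUE)
  merged <- GenomicRanges::sort(merged)
  ov <- GenomicRanges::findOverlaps(gr, merged)
  block_of <- integer(length(gr))
  block_of[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  ids <- sprintf("MB%05d", seq_along(merged))
  blocks <- data.frame(
    block_id = ids,
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    n_members = as.integer(table(factor(block_of,
                                        levels = seq_along(merged)))),
    stringsAsFactors = FALSE)
  alignments$block_id <- ids[block_of]
  list(blocks = blocks, alignments = alignments)
}

#' Unique-length deduplication counts
#'
#' PCR duplicates of one molecule share its exact fragment length;
#' original molecules of one site differ in length. The molecule count
#' for a (block, arm, replicate) cell is therefore the cardinality of its
#' set of flank lengths, and the pooled count the cardinality of the
#' union over replicates.
#'
#' @param alignments data.frame with `block_id`, `arm`, `replicate`,
#'   `flank_length`.
#' @return data.frame with one row per (block_id, arm): columns `A`, `B`,
#'   `C` (per-replicate unique-length counts) and `pooled`.
#' @export
dedup_unique_lengths <- function(alignments) {
  if (nrow(alignments) == 0) {
    return(data.frame(block_id = character(0), arm = character(0),
                      A = integer(0), B = integer(0), C = integer(0),
                      pooled = integer(0), stringsAsFactors = FALSE))
  }
  key <- interaction(alignments$block_id, alignments$arm, drop = TRUE)
  out <- lapply(split(alignments, key), function(d) {
    per_rep <- vapply(c("A", "B", "C"), function(r)
      length(unique(d$flank_length[d$replicate == r])), integer(1))
    data.frame(block_id = d$block_id[1], arm = d$arm[1],
               A = per_rep[["A"]], B = per_rep[["B"]], C = per_rep[["C"]],
               pooled = length(unique(d$flank_length)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$block_id, out$arm), , drop = FALSE]
}

# Pyramid check: reads of an authentic site share one junction end and
# shrink away from it, so per-base coverage is maximal at the junction
# and non-increasing with distance in the read direction.
stack_pyramid_ok <- function(d, junction, strand, tolerance, min_stack) {
  at_junction <- abs(d$junction_pos - junction) <= tolerance
  if (length(unique(d$flank_length[at_junction])) < min_stack) return(FALSE)
  lo <- min(d$start); hi <- max(d$end)
  cov <- integer(hi - lo)
  for (i in seq_len(nrow(d))) {
    span <- (d$start[i] - lo + 1L):(d$end[i] - lo)
    cov[span] <- cov[span] + 1L
  }
  prof <- if (strand == "+") cov[(junction - lo + 1L):length(cov)] else
    rev(cov[1:(junction - lo + 1L)])
  all(diff(prof) <= 0L)
}

#' Call integration sites per master block and arm
#'
#' The site junction is the modal tag-adjacent coordinate (ties toward
#' the smaller coordinate) and the site strand the majority strand;
#' molecule counts come from [dedup_unique_lengths()]. `stack_ok` is true
#' when at least `min_stack` distinct lengths share the modal junction
#' within `junction_tolerance` and coverage is non-increasing with
#' distance from the junction (the pyramidal read stack of linear
#' amplification).
#'
#' @param blocks result of [build_master_blocks()].
#' @param junction_tolerance tolerance (bp) absorbing alignment jitter at
#'   the junction.
#' @param min_stack minimum distinct lengths at the modal junction.
#' @return data.frame of site calls: `block_id`, `arm`, `chrom`,
#'   `junction_pos`, `strand`, `minority_strand_frac`, `A`, `B`, `C`,
#'   `pooled`, `median_read_sample`, `stack_ok`.
#' @export
call_sites <- function(blocks, junction_tolerance = 2L, min_stack = 3L) {
  aln <- blocks$alignments
  if (nrow(aln) == 0) {
    return(data.frame(block_id = character(0), arm = character(0),
                      chrom = character(0), junction_pos = integer(0),
                      strand = character(0), minority_strand_frac = numeric(0),
                      A = integer(0), B = integer(0), C = integer(0),
                      pooled = integer(0), median_read_sample = numeric(0),
                      stack_ok = logical(0), stringsAsFactors = FALSE))
  }
  counts <- dedup_unique_lengths(aln)
  key <- interaction(aln$block_id, aln$arm, drop = TRUE)
  calls <- lapply(split(aln, key), function(d) {
    strand_tab <- table(d$strand)
    strand <- names(strand_tab)[which.max(strand_tab)]
    minority <- 1 - max(strand_tab) / sum(strand_tab)
    junction <- stat_mode(d$junction_pos)
    data.frame(block_id = d$block_id[1], arm = d$arm[1], chrom = d$chrom[1],
               junction_pos = junction, strand = strand,
               minority_strand_frac = minority,
               stack_ok = stack_pyramid_ok(d, junction, strand,
                                           junction_tolerance, min_stack),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  out <- merge(calls, counts, by = c("block_id", "arm"), sort = FALSE)
  out$median_read_sample <- apply(out[, c("A", "B", "C")], 1, median)
  out <- out[order(out$block_id, out$arm),
             c("block_id", "arm", "chrom", "junction_pos", "strand",
               "minority_strand_frac", "A", "B", "C", "pooled",
               "median_read_sample", "stack_ok")]
  rownames(out) <- NULL
  out
}

#' Replicate concordance (pairwise Spearman)
#'
#' Rank correlation of per-site unique-molecule counts between the three
#' replicate reactions, ties handled by average ranks. Undefined (NA)
#' with fewer than three sites with nonzero counts.
#'
#' @param sites site calls from [call_sites()] (one arm at a time is
#'   conventional; pass a subset).
#' @return named numeric vector `AB`, `AC`, `BC`.
#' @export
replicate_concordance <- function(sites) {
  keep <- sites$A + sites$B + sites$C > 0
  s <- sites[keep, , drop = FALSE]
  pairs <- list(AB = c("A", "B"), AC = c("A", "C"), BC = c("B", "C"))
  if (nrow(s) < 3) return(setNames(rep(NA_real_, 3), names(pairs)))
  vapply(pairs, function(p) cor(s[[p[1]]], s[[p[2]]], method = "spearman"),
         numeric(1))
}
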
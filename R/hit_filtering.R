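# The screen's filter ledger and hit-table aggregation.
#
# Filters are independent predicates over site calls: composing them in
# any order yields the same survivor set. The reporting order is fixed
# (read depth -> orientation/stack -> control subtraction -> genic/fusion)
# so that the per-filter trace is reproducible.

#' Filter ledger configuration
#'
#' @param min_unique_reads minimum pooled unique-length reads for a site
#'   to survive (sites with fewer are discarded).
#' @param high_depth_threshold pooled unique-read count above which
#'   (strictly) a site is tiered high-depth; descriptive by default, a
#'   discard rule when `hard_depth_filter = TRUE`.
#' @param control_presence_min minimum pooled unique-length reads in the
#'   control arm of the same master block for an experimental site to be
#'   treated as a shared false positive and discarded.
#' @param require_genic discard sites outside known genes.
#' @param require_fusion_viable discard sites whose splicing cannot yield
#'   an in-frame reporter fusion.
#' @param orientation_mode `"same"` when a productive trap lays junction
#'   reads on the host gene's strand (default convention), `"opposite"`
#'   for the mirrored chemistry.
#' @param hard_depth_filter make the high-depth tier a discard filter.
#' @return list of class `filter_ledger`.
#' @export
filter_ledger <- function(min_unique_reads = 3L,
                          high_depth_threshold = 30L,
                          control_presence_min = 1L,
                          require_genic = TRUE,
                          require_fusion_viable = TRUE,
                          orientation_mode = c("same", "opposite"),
                          hard_depth_filter = FALSE) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(min_unique_reads >= 1,
            high_depth_threshold >= min_unique_reads,
            control_presence_min >= 1)
  structure(as.list(environment()), class = "filter_ledger")
}

#' Read-depth filter
#'
#' A site survives iff its pooled unique-length read count reaches
#' `min_unique_reads` (default 3: sites with fewer than three
#' unique-length reads are discarded).
#'
#' @param sites site calls (data.frame with `pooled`).
#' @param ledger a [filter_ledger()].
#' @return logical vector, TRUE for survivors.
#' @export
filter_min_reads <- function(sites, ledger = filter_ledger()) {
  sites$pooled >= ledger$min_unique_reads
}

#' Orientation / read-stack filter
#'
#' An authentic integration produces a pyramidal stack of co-oriented
#' reads sharing the junction; a site survives iff `stack_ok` holds and,
#' for genic sites, its strand matches the host gene's transcription
#' direction under the configured orientation convention. Anti-oriented
#' sites are discarded; intergenic sites pass unchanged (they are handled
#' by the genic/fusion filter).
#'
#' @param sites site calls.
#' @param ann a `trap_annotation`.
#' @param ledger a [filter_ledger()].
#' @return logical vector, TRUE for survivors.
#' @export
filter_orientation_stack <- function(sites, ann, ledger = filter_ledger()) {
  vapply(seq_len(nrow(sites)), function(i) {
    if (!sites$stack_ok[i]) return(FALSE)
    ctx <- locate_insertion(ann, sites$chrom[i], sites$junction_pos[i],
                            sites$strand[i])
    if (ctx$status == "intergenic") return(TRUE)
    expected <- if (ledger$orientation_mode == "same") ctx$gene_strand else
      setdiff(c("+", "-"), ctx$gene_strand)
    sites$strand[i] == expected
  }, logical(1))
}

#' Negative-control subtraction
#'
#' An experimental site is discarded when the same master block carries
#' at least `control_presence_min` pooled unique-length reads in the
#' negative-control arm.
#'
#' @param sites experimental-arm site calls.
#' @param control_sites control-arm site calls (may be empty; the filter
#'   is then skipped with a warning).
#' @param ledger a [filter_ledger()].
#' @return logical vector, TRUE for survivors.
#' @export
subtract_control <- function(sites, control_sites,
                             ledger = filter_ledger()) {
  if (is.null(control_sites) || nrow(control_sites) == 0) {
    warning("control arm absent: negative-control subtraction skipped")
    return(rep(TRUE, nrow(sites)))
  }
  hot <- control_sites$block_id[control_sites$pooled >=
                                  ledger$control_presence_min]
  !(sites$block_id %in% hot)
}

#' Genic / fusion-viability filter
#'
#' A site survives iff it falls inside a known gene and its precise
#' location supports an in-frame reporter fusion (intronic, downstream
#' of at least one complete coding codon, co-directional). Survivors are
#' annotated with the host gene, intron index, matching frame variant,
#' truncation length and protein length.
#'
#' @param sites site calls.
#' @param ann a `trap_annotation`.
#' @param ledger a [filter_ledger()].
#' @return list with `keep` (logical vector) and `annotation`
#'   (data.frame of per-site fusion annotations, rows aligned to
#'   `sites`).
#' @export
filter_genic_fusion <- function(sites, ann, ledger = filter_ledger()) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    ctx <- locate_insertion(ann, sites$chrom[i], sites$junction_pos[i],
                            sites$strand[i])
    fp <- predict_fusion(ctx)
    genic <- !ctx$status %in% c("intergenic", "outside_transcript") &&
      isTRUE(ctx$orientation_match)
    data.frame(
      gene_id = if (is.null(ctx$gene_id) || !genic) NA_character_ else
        ctx$gene_id,
      gene_name = if (is.null(ctx$gene_name) || !genic) NA_character_ else
        ctx$gene_name,
      status = ctx$status,
      intron_index = fp$intron_index %||% NA_integer_,
      upstream_cds_nt = fp$upstream_cds_nt,
      matching_variant = if (length(fp$matching_variants))
        fp$matching_variants[1] else NA_integer_,
      truncation_aa = fp$truncation_aa,
      protein_length_aa = ctx$protein_length_aa %||% NA_integer_,
      fusion_viable = fp$viable,
      stringsAsFactors = FALSE)
  })
  annotation <- do.call(rbind, rows)
  keep <- rep(TRUE, nrow(sites))
  if (ledger$require_genic) keep <- keep & !is.na(annotation$gene_id)
  if (ledger$require_fusion_viable) keep <- keep & annotation$fusion_viable
  list(keep = keep, annotation = annotation)
}

#' Read-depth tiering
#'
#' A site is high-depth iff its pooled unique-read count strictly exceeds
#' `high_depth_threshold` (default "> 30 reads/site"). Descriptive
#' stratification, not a discard rule, unless `hard_depth_filter` is set
#' in the ledger.
#'
#' @param sites site calls.
#' @param ledger a [filter_ledger()].
#' @return character vector, `"high"` or `"long_tail"` per site.
#' @export
tier_by_depth <- function(sites, ledger = filter_ledger()) {
  out <- rep("long_tail", nrow(sites))
  out[sites$pooled > ledger$high_depth_threshold] <- "high"
  out
}

#' Apply the full filter ledger
#'
#' Applies, in reporting order, the read-depth filter, the
#' orientation/read-stack filter, negative-control subtraction, and the
#' genic/fusion-viability filter. The survivor set is order-independent
#' (all filters are independent predicates); the trace is not.
#'
#' @param sites experimental-arm site calls from [call_sites()].
#' @param control_sites control-arm site calls (or NULL).
#' @param ann a `trap_annotation`.
#' @param ledger a [filter_ledger()].
#' @return list with `survivors` (annotated site calls), `discards`
#'   (sites plus `failed_filter`), and `trace` (per-filter in/out/discard
#'   counts).
#' @export
apply_filter_ledger <- function(sites, control_sites, ann,
                                ledger = filter_ledger()) {
  fg <- filter_genic_fusion(sites, ann, ledger)
  sites <- cbind(sites, fg$annotation)
  sites$depth_tier <- tier_by_depth(sites, ledger)
  pass <- list(
    min_reads = filter_min_reads(sites, ledger),
    orientation_stack = filter_orientation_stack(sites, ann, ledger),
    control_subtraction = subtract_control(sites, control_sites, ledger),
    genic_fusion = fg$keep)
  if (ledger$hard_depth_filter) {
    pass$high_depth <- sites$depth_tier == "high"
  }
  alive <- rep(TRUE, nrow(sites))
  trace <- list()
  failed <- rep(NA_character_, nrow(sites))
  for (f in names(pass)) {
    n_in <- sum(alive)
    drop_now <- alive & !pass[[f]]
    failed[drop_now] <- f
    alive <- alive & pass[[f]]
    trace[[f]] <- data.frame(filter = f, n_in = n_in, n_out = sum(alive),
                             n_discarded = sum(drop_now))
  }
  discards <- sites[!alive, , drop = FALSE]
  discards$failed_filter <- failed[!alive]
  list(survivors = sites[alive, , drop = FALSE],
       discards = discards,
       trace = do.call(rbind, trace))
}

#' Aggregate surviving sites into a hit table
#'
#' One record per surviving site, annotated per gene with the number of
#' independently identified integration sites; genes with two or more
#' sites are tiered `high_confidence`. Positions are reported 1-based.
#' Rows are sorted by tier (high-confidence first), gene and position.
#'
#' @param sites annotated surviving sites: data.frame with `chrom`,
#'   `strand`, a position column (`junction_pos` 0-based or
#'   `insertion_site` 1-based), `median_read_sample`, `gene_id`,
#'   `gene_name`, `truncation_aa`, `protein_length_aa`.
#' @return data.frame hit table with columns `chrom`, `strand`,
#'   `insertion_site` (1-based), `median_read_sample`,
#'   `n_insertion_sites_in_gene`, `gene_name`, `gene_id`,
#'   `truncation_aa`, `protein_length_aa`, `tier`.
#' @export
aggregate_hits <- function(sites) {
  cols <- c("chrom", "strand", "insertion_site", "median_read_sample",
            "n_insertion_sites_in_gene", "gene_name", "gene_id",
            "truncation_aa", "protein_length_aa", "tier")
  if (nrow(sites) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
    return(out)
  }
  insertion_site <- if ("insertion_site" %in% names(sites))
    sites$insertion_site else sites$junction_pos + 1L
  hits <- data.frame(chrom = as.character(sites$chrom),
                     strand = sites$strand,
                     insertion_site = insertion_site,
                     median_read_sample = sites$median_read_sample,
                     gene_name = sites$gene_name, gene_id = sites$gene_id,
                     truncation_aa = sites$truncation_aa,
                     protein_length_aa = sites$protein_length_aa,
                     stringsAsFactors = FALSE)
  n_by_gene <- table(hits$gene_id)
  hits$n_insertion_sites_in_gene <- as.integer(n_by_gene[hits$gene_id])
  hits$tier <- ifelse(hits$n_insertion_sites_in_gene >= 2,
                      "high_confidence", "single_site")
  hits <- hits[order(hits$tier != "high_confidence", hits$gene_name,
                     hits$insertion_site), cols]
  rownames(hits) <- NULL
  hits
}
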
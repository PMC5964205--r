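# End-to-end orchestration: trim -> map -> master blocks -> site calls
# -> filter ledger -> hit table, with per-stage record counts and a QC
# report, plus truth-table evaluation for simulated runs.

#' Run the insertion-site deconvolution pipeline
#'
#' Executes every stage over a FASTQ manifest (one file per arm x
#' replicate), persists intermediates when `out_dir` is given, and
#' returns all stage tables. Stage record counts are collected in
#' `$log`.
#'
#' @param manifest data.frame with columns `file`, `arm`
#'   (`"experimental"`/`"control"`), `replicate` (`"A"/"B"/"C"`); or the
#'   result of [simulate_screen()] (its FASTQ manifest is used).
#' @param genome `DNAStringSet` (or FASTA path).
#' @param annotation `trap_annotation` (or GTF path).
#' @param tag junction tag to trim.
#' @param max_tag_mismatch,min_flank trimming parameters; see
#'   [trim_tag()].
#' @param seed_len,max_mismatch mapping parameters; see [map_flank()].
#' @param junction_tolerance,min_stack site-calling parameters; see
#'   [call_sites()].
#' @param ledger a [filter_ledger()].
#' @param out_dir optional directory for persisted TSV/JSON outputs.
#' @return list with `hits`, `survivors`, `discards`, `trace`, `sites`
#'   (all arms), `site_calls_experimental`, `site_calls_control`,
#'   `blocks`, `alignments`, `qc` (replicate concordance), `log`.
#' @export
run_screen_pipeline <- function(manifest, genome, annotation,
                                tag = TOL2_TAG,
                                max_tag_mismatch = 2L, min_flank = 25L,
                                seed_len = 20L, max_mismatch = 2L,
                                junction_tolerance = 2L, min_stack = 3L,
                                ledger = filter_ledger(),
                                out_dir = NULL) {
  if (!is.null(manifest$dir) && !is.null(manifest$manifest)) {
    mf <- jsonlite::read_json(manifest$manifest, simplifyVector = TRUE)
    manifest <- mf$fastq
  }
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  # the annotation is resolved against this reference: chromosomes that
  # carry no gene are still valid lookup targets (intergenic)
  annotation$chroms <- union(annotation$chroms, names(genome))
  if (nrow(manifest) > 0) {
    key <- paste(manifest$arm, manifest$replicate)
    if (anyDuplicated(key)) stop("manifest maps one (arm, replicate) to ",
                                 "multiple FASTQ files")
    missing <- !file.exists(manifest$file)
    if (any(missing)) stop("manifest FASTQ not found: ",
                           manifest$file[missing][1])
  }
  log <- list()
  aln_all <- list()
  for (i in seq_len(nrow(manifest))) {
    reads <- read_fastq(manifest$file[i])
    tr <- trim_tag(reads, tag = tag, max_mismatch = max_tag_mismatch,
                   min_flank = min_flank)
    mp <- map_flank(tr$trimmed, genome, seed_len = seed_len,
                    max_mismatch = max_mismatch)
    aln <- mp$alignments
    if (nrow(aln) > 0) {
      aln$arm <- manifest$arm[i]
      aln$replicate <- manifest$replicate[i]
    }
    aln_all[[i]] <- aln
    log[[i]] <- data.frame(
      arm = manifest$arm[i], replicate = manifest$replicate[i],
      reads_in = nrow(reads), trimmed = nrow(tr$trimmed),
      trim_rejected = nrow(tr$rejected), mapped = nrow(aln),
      map_rejected = nrow(mp$rejected))
  }
  alignments <- if (length(aln_all)) do.call(rbind, aln_all) else
    data.frame(read_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               junction_pos = integer(0), flank_length = integer(0),
               mismatches = integer(0), arm = character(0),
               replicate = character(0))
  log <- if (length(log)) do.call(rbind, log) else data.frame()

  blocks <- build_master_blocks(alignments)
  sites <- call_sites(blocks, junction_tolerance = junction_tolerance,
                      min_stack = min_stack)
  exp_sites <- sites[sites$arm == "experimental", , drop = FALSE]
  ctl_sites <- sites[sites$arm == "control", , drop = FALSE]
  qc <- list(concordance_experimental = replicate_concordance(exp_sites),
             concordance_control = replicate_concordance(ctl_sites),
             replicates = sort(unique(alignments$replicate)))
  filtered <- if (nrow(exp_sites) > 0) {
    apply_filter_ledger(exp_sites, ctl_sites, annotation, ledger)
  } else {
    list(survivors = exp_sites, discards = exp_sites, trace = data.frame())
  }
  hits <- if (nrow(filtered$survivors) > 0) {
    aggregate_hits(filtered$survivors)
  } else {
    aggregate_hits(data.frame())
  }
  res <- list(hits = hits, survivors = filtered$survivors,
              discards = filtered$discards, trace = filtered$trace,
              sites = sites, site_calls_experimental = exp_sites,
              site_calls_control = ctl_sites, blocks = blocks$blocks,
              alignments = blocks$alignments, qc = qc, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(hits, "hit_table.tsv")
    wt(filtered$discards, "discards.tsv")
    wt(sites, "site_calls.tsv")
    wt(blocks$blocks, "master_blocks.tsv")
    wt(log, "stage_counts.tsv")
    if (nrow(filtered$trace) > 0) wt(filtered$trace, "filter_trace.tsv")
    jsonlite::write_json(
      list(concordance_experimental = as.list(qc$concordance_experimental),
           concordance_control = as.list(qc$concordance_control),
           replicates = qc$replicates),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Build site calls from simulator truth assignments
#'
#' Converts the per-read truth table of [simulate_reads()] directly into
#' alignments (bypassing the mapper), then builds master blocks and site
#' calls. Used for fast replicate-concordance studies where only the
#' subsampling and deduplication structure matters.
#'
#' @param reads per-read truth data.frame from [simulate_reads()].
#' @return site calls as from [call_sites()].
#' @export
call_sites_from_truth <- function(reads) {
  if (nrow(reads) == 0) return(call_sites(build_master_blocks(
    data.frame(chrom = character(0), start = integer(0), end = integer(0)))))
  start <- ifelse(reads$orientation == "+", reads$junction,
                  reads$junction - reads$flank_length + 1L)
  aln <- data.frame(read_id = reads$read_id, chrom = reads$chrom,
                    start = as.integer(start),
                    end = as.integer(start + reads$flank_length),
                    strand = reads$orientation,
                    junction_pos = reads$junction,
                    flank_length = reads$flank_length,
                    mismatches = 0L, arm = reads$arm,
                    replicate = reads$replicate, stringsAsFactors = FALSE)
  call_sites(build_master_blocks(aln))
}

#' Evaluate a pipeline run against the simulation truth table
#'
#' Matches hit-table records to planted events by junction coordinate
#' (within `tolerance`), and reports recall over true traps — overall and
#' restricted to traps that retained at least `min_unique_reads` pooled
#' unique-length reads in the experimental site calls — plus the count of
#' decoys of any class appearing among the hits.
#'
#' @param result list from [run_screen_pipeline()].
#' @param events truth events from [sample_insertions()].
#' @param tolerance junction matching tolerance (bp).
#' @param min_unique_reads recoverability threshold for the restricted
#'   recall denominator.
#' @return list with `n_hits`, `recall_all`, `recall_recoverable`,
#'   `n_true_recovered`, `n_true_recoverable`, `n_decoy_hits`, and the
#'   joined `events` table (per-event `recovered`, `site_pooled`).
#' @export
evaluate_screen <- function(result, events, tolerance = 2L,
                            min_unique_reads = 3L) {
  hits <- result$hits
  match_hit <- function(chrom, pos0) {
    any(hits$chrom == chrom & abs(hits$insertion_site - 1L - pos0) <=
          tolerance)
  }
  events$recovered <- vapply(seq_len(nrow(events)), function(i)
    match_hit(events$chrom[i], events$pos[i]), logical(1))
  sc <- result$site_calls_experimental
  events$site_pooled <- vapply(seq_len(nrow(events)), function(i) {
    m <- sc$chrom == events$chrom[i] &
      abs(sc$junction_pos - events$pos[i]) <= tolerance
    if (any(m)) max(sc$pooled[m]) else 0L
  }, integer(1))
  true_ev <- events[events$event_class == "true_trap", , drop = FALSE]
  recoverable <- true_ev$site_pooled >= min_unique_reads
  decoy_ev <- events[events$event_class != "true_trap", , drop = FALSE]
  list(n_hits = nrow(hits),
       recall_all = if (nrow(true_ev)) mean(true_ev$recovered) else
         NA_real_,
       recall_recoverable = if (any(recoverable))
         mean(true_ev$recovered[recoverable]) else NA_real_,
       n_true_recovered = sum(true_ev$recovered),
       n_true_recoverable = sum(recoverable),
       n_decoy_hits = sum(decoy_ev$recovered),
       events = events)
}

#' Load the published screen hit list
#'
#' Per-site records of the CAL51 PAR-biosensor gene-trap screen's final
#' hit table (20 insertion sites in 17 genes), shipped with the package
#' as a plain-text fixture for worked examples and aggregation checks.
#'
#' @param path optional override of the fixture location.
#' @return data.frame with columns `chrom`, `strand`, `insertion_site`
#'   (1-based), `median_read_sample`, `n_insertion_sites_reported`,
#'   `gene_name`, `gene_id`, `truncation_aa`, `protein_length_aa`.
#' @export
published_screen_hits <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parylation_screen_hits.tsv",
                        package = "trapscreen")
  }
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    chrom = "character"))
}
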
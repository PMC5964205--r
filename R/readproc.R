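# Junction-tag trimming and desk-scale flank mapping.
#
# The built-in mapper is exact-seed (first 20 nt of the flank) plus
# full-length Hamming extension with a mismatch cap. It exists so that
# toy-genome runs are verifiable end to end; real-data scale delegates to
# an external aligner via import_alignments().

#' Trim the transposon junction tag from reads
#'
#' A read is kept when its prefix matches `tag` within `max_mismatch`
#' substitutions (no indels); the remainder is the genomic flank.
#' Ambiguous bases in the tag region count as mismatches. A second exact
#' tag occurrence inside the flank (transposon concatemer) truncates the
#' flank there and flags the read.
#'
#' @param reads data.frame with columns `read_id`, `seq` (e.g. from
#'   [read_fastq()]); extra columns are carried through.
#' @param tag junction tag sequence (default the 23-nt Tol2 tag).
#' @param max_mismatch maximum substitutions tolerated in the tag prefix.
#' @param min_flank minimum flank length retained after trimming.
#' @return list with `trimmed` (input columns plus `flank`,
#'   `flank_length`, `concatemer`) and `rejected` (columns `read_id`,
#'   `reason` in `{"empty", "no_tag", "too_short"}`).
#' @export
trim_tag <- function(reads, tag = TOL2_TAG, max_mismatch = 2L,
                     min_flank = 25L) {
  stopifnot(nzchar(tag))
  n <- nrow(reads)
  if (n == 0) {
    return(list(trimmed = cbind(reads, flank = character(0),
                                flank_length = integer(0),
                                concatemer = logical(0)),
                rejected = data.frame(read_id = character(0),
                                      reason = character(0))))
  }
  tlen <- nchar(tag)
  reason <- rep(NA_character_, n)
  reason[nchar(reads$seq) == 0] <- "empty"
  long_enough <- nchar(reads$seq) >= tlen
  mm <- rep(tlen, n)
  mm[long_enough] <- prefix_mismatches(reads$seq[long_enough], tag)
  reason[is.na(reason) & mm > max_mismatch] <- "no_tag"
  flank <- substr(reads$seq, tlen + 1L, nchar(reads$seq))
  # concatemer truncation: exact second tag occurrence inside the flank
  second <- regexpr(tag, flank, fixed = TRUE)
  concatemer <- is.na(reason) & second > 0
  flank[concatemer] <- substr(flank[concatemer], 1L,
                              second[concatemer] - 1L)
  reason[is.na(reason) & nchar(flank) < min_flank] <- "too_short"
  keep <- is.na(reason)
  trimmed <- reads[keep, , drop = FALSE]
  trimmed$flank <- flank[keep]
  trimmed$flank_length <- nchar(flank[keep])
  trimmed$concatemer <- concatemer[keep]
  rownames(trimmed) <- NULL
  list(trimmed = trimmed,
       rejected = data.frame(read_id = reads$read_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

# Internal genome index for the mapper: character and raw forms of each
# chromosome and its reverse complement.
genome_index <- function(genome) {
  chr <- as.character(genome)
  rc <- vapply(chr, revcomp_chr, character(1), USE.NAMES = FALSE)
  names(rc) <- names(chr)
  list(fwd = chr, rev = rc,
       fwd_raw = lapply(chr, charToRaw), rev_raw = lapply(rc, charToRaw),
       lens = nchar(chr))
}

#' Map trimmed flanks to the reference genome
#'
#' Exact-seed / Hamming-extension mapping on both strands. A flank is
#' placed at its unique best location (fewest mismatches); ties across
#' distinct loci are rejected as `multimapped`, and flanks with no
#' placement within `max_mismatch` as `unmapped`. For a `+` strand
#' placement the junction is the interval start; for `-` it is the last
#' base of the interval (the tag-adjacent end).
#'
#' @param trimmed data.frame from [trim_tag()]`$trimmed` (columns
#'   `read_id`, `flank`, `flank_length`; `arm`/`replicate` carried
#'   through when present).
#' @param genome `DNAStringSet` from [read_genome()].
#' @param seed_len exact-match seed length (first bases of the flank).
#' @param max_mismatch maximum substitutions over the full flank.
#' @return list with `alignments` (`read_id`, `chrom`, `start`, `end`
#'   0-based half-open, `strand`, `junction_pos`, `flank_length`,
#'   `mismatches`, plus carried columns) and `rejected` (`read_id`,
#'   `reason` in `{"unmapped", "multimapped"}`).
#' @export
map_flank <- function(trimmed, genome, seed_len = 20L, max_mismatch = 2L) {
  carry <- intersect(c("arm", "replicate", "event_id"), names(trimmed))
  empty_aln <- data.frame(read_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), junction_pos = integer(0),
                          flank_length = integer(0), mismatches = integer(0),
                          stringsAsFactors = FALSE)
  if (nrow(trimmed) == 0) {
    return(list(alignments = empty_aln,
                rejected = data.frame(read_id = character(0),
                                      reason = character(0))))
  }
  if (any(grepl("[^ACGTN]", trimmed$flank))) {
    stop("flank contains non-ACGTN characters")
  }
  idx <- genome_index(genome)
  flanks <- trimmed$flank
  uniq <- unique(flanks)
  # candidate seed positions: exact match of the first seed_len bases,
  # searched on the forward genome and on its reverse complement
  if (any(trimmed$flank_length < seed_len)) {
    stop("flank shorter than the mapper seed (", seed_len, " nt)")
  }
  seeds <- substr(uniq, 1L, seed_len)
  # seeds containing N cannot seed an exact match; force them unmapped
  seed_has_n <- grepl("N", seeds, fixed = TRUE)
  seeds[seed_has_n] <- strrep("A", seed_len)  # placeholder; skipped below
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  hits <- list(fwd = list(), rev = list())
  for (space in c("fwd", "rev")) {
    for (chrom in names(idx[[space]])) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(
        idx[[space]][[chrom]]))
      nh <- S4Vectors::elementNROWS(m)
      # flat positions + per-seed offsets: cheap slicing in the hot loop
      hits[[space]][[chrom]] <- list(
        flat = IRanges::start(BiocGenerics::unlist(m)),
        off = cumsum(c(0L, nh)), n = nh)
    }
  }
  uraw <- lapply(uniq, charToRaw)
  place_one <- function(u) {
    if (seed_has_n[u]) return(c(-1L, 0L, 0L, 0L))
    fl_raw <- uraw[[u]]
    L <- length(fl_raw)
    best_mm <- max_mismatch + 1L
    best <- NULL; nbest <- 0L
    for (space in c("fwd", "rev")) {
      raws <- if (space == "fwd") idx$fwd_raw else idx$rev_raw
      for (chrom in names(raws)) {
        h <- hits[[space]][[chrom]]
        if (h$n[u] == 0L) next
        starts <- h$flat[(h$off[u] + 1L):(h$off[u] + h$n[u])]
        cl <- idx$lens[[chrom]]
        for (s in starts) {
          if (s + L - 1L > cl) next
          mm <- raw_mismatches(fl_raw, raws[[chrom]][s:(s + L - 1L)])
          if (mm > max_mismatch) next
          if (mm < best_mm) {
            best_mm <- mm; nbest <- 1L
            best <- c(space == "rev", match(chrom, names(raws)), s)
          } else if (mm == best_mm) {
            nbest <- nbest + 1L
          }
        }
      }
    }
    if (is.null(best) || best_mm > max_mismatch) return(c(-1L, 0L, 0L, 0L))
    if (nbest > 1L) return(c(-2L, 0L, 0L, 0L))
    c(best_mm, best)
  }
  placements <- vapply(seq_along(uniq), place_one, numeric(4))
  pl <- placements[, match(flanks, uniq), drop = FALSE]

  status <- pl[1, ]
  ok <- status >= 0
  rejected <- data.frame(
    read_id = trimmed$read_id[!ok],
    reason = ifelse(status[!ok] == -1, "unmapped", "multimapped"),
    stringsAsFactors = FALSE)
  if (!any(ok)) return(list(alignments = empty_aln, rejected = rejected))

  is_rev <- pl[2, ok] == 1
  chrom_i <- pl[3, ok]
  s_in_space <- pl[4, ok]             # 1-based within fwd or revcomp space
  L <- trimmed$flank_length[ok]
  chrom <- names(idx$fwd)[chrom_i]
  clen <- unname(idx$lens[chrom_i])
  # convert revcomp-space matches back to forward coordinates (0-based)
  start0 <- ifelse(is_rev, clen - (s_in_space - 1L) - L, s_in_space - 1L)
  end0 <- start0 + L
  strand <- ifelse(is_rev, "-", "+")
  junction <- ifelse(strand == "+", start0, end0 - 1L)
  aln <- data.frame(read_id = trimmed$read_id[ok], chrom = chrom,
                    start = as.integer(start0), end = as.integer(end0),
                    strand = strand, junction_pos = as.integer(junction),
                    flank_length = as.integer(L),
                    mismatches = as.integer(pl[1, ok]),
                    stringsAsFactors = FALSE)
  for (cc in carry) aln[[cc]] <- trimmed[[cc]][ok]
  rownames(aln) <- NULL
  list(alignments = aln, rejected = rejected)
}

#' Export alignments to BED6
#'
#' Name carries the read id and score the mismatch count.
#'
#' @param alignments data.frame from [map_flank()]`$alignments`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
export_alignments_bed <- function(alignments, path) {
  bed <- data.frame(chrom = alignments$chrom, start = alignments$start,
                    end = alignments$end, name = alignments$read_id,
                    score = alignments$mismatches,
                    strand = alignments$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Import externally produced alignments (BED6 or SAM)
#'
#' The junction coordinate is recomputed from the strand convention
#' (interval start on `+`, last interval base on `-`), and the aligned
#' reference span is used as the fragment length. SAM input keeps primary
#' mapped records only.
#'
#' @param path BED6 or SAM file (format inferred from extension unless
#'   given).
#' @param format `"bed"` or `"sam"`.
#' @param arm,replicate sample labels attached to every record; when
#'   `NULL` they are parsed from a `<arm>_<replicate>` filename prefix.
#' @param genome optional `DNAStringSet` used to validate coordinates.
#' @return data.frame of alignments in the [map_flank()] layout.
#' @export
import_alignments <- function(path, format = c("auto", "bed", "sam"),
                              arm = NULL, replicate = NULL, genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  if (is.null(arm) || is.null(replicate)) {
    base <- sub("\\.[^.]*$", "", basename(path))
    parts <- strsplit(base, "_")[[1]]
    if (is.null(arm)) arm <- parts[1]
    if (is.null(replicate) && length(parts) > 1) replicate <- parts[2]
    if (is.null(replicate)) replicate <- NA_character_
  }
  if (format == "bed") {
    if (file.info(path)$size == 0) {
      df <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), name = character(0),
                       score = integer(0), strand = character(0))
    } else {
      df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(df) < 6) stop("BED records missing strand field: ", path)
      names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    }
    aln <- data.frame(read_id = as.character(df$name), chrom = df$chrom,
                      start = as.integer(df$start),
                      end = as.integer(df$end),
                      strand = as.character(df$strand),
                      mismatches = as.integer(df$score),
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^@", lines) & nzchar(lines)]
    recs <- lapply(lines, function(l) strsplit(l, "\t")[[1]])
    keep <- vapply(recs, function(f) {
      flag <- as.integer(f[2])
      bitwAnd(flag, 4L) == 0L && bitwAnd(flag, 256L) == 0L &&
        bitwAnd(flag, 2048L) == 0L
    }, logical(1))
    recs <- recs[keep]
    if (length(recs) == 0) {
      aln <- data.frame(read_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), mismatches = integer(0),
                        stringsAsFactors = FALSE)
    } else {
      ref_width <- vapply(recs, function(f) {
        ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
        n <- as.integer(sub("[A-Z=]", "", ops))
        sum(n[grepl("[MDN=X]", ops)])
      }, integer(1))
      aln <- data.frame(
        read_id = vapply(recs, `[`, character(1), 1),
        chrom = vapply(recs, `[`, character(1), 3),
        start = vapply(recs, function(f) as.integer(f[4]) - 1L, integer(1)),
        end = vapply(recs, function(f) as.integer(f[4]) - 1L, integer(1)) +
          ref_width,
        strand = vapply(recs, function(f)
          if (bitwAnd(as.integer(f[2]), 16L)) "-" else "+", character(1)),
        mismatches = 0L, stringsAsFactors = FALSE)
    }
  }
  if (nrow(aln) > 0 && any(!aln$strand %in% c("+", "-"))) {
    stop("alignment records missing strand")
  }
  if (!is.null(genome) && nrow(aln) > 0) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    bad <- is.na(lens[aln$chrom]) | aln$end > lens[aln$chrom] | aln$start < 0
    if (any(bad)) stop("alignment coordinates beyond chromosome length")
  }
  aln$junction_pos <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  aln$flank_length <- aln$end - aln$start
  aln$arm <- rep(arm, nrow(aln))
  aln$replicate <- rep(replicate, nrow(aln))
  aln[, c("read_id", "chrom", "start", "end", "strand", "junction_pos",
          "flank_length", "mismatches", "arm", "replicate")]
}
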
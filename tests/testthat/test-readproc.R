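tag <- "TTTGAGTACTTTTTACACCTCTG"

test_that("trim_tag trims exact and near-matching tag prefixes", {
  flank <- strrep("ACGT", 10)
  reads <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                      seq = c(paste0(tag, flank),
                              paste0("GGGG", flank),
                              paste0(sub("^T", "A", tag), flank),
                              ""),
                      stringsAsFactors = FALSE)
  out <- trim_tag(reads, tag, max_mismatch = 1)
  expect_identical(out$trimmed$read_id, c("r1", "r3"))
  expect_identical(out$trimmed$flank, c(flank, flank))
  expect_identical(sort(out$rejected$reason), c("empty", "no_tag"))

  strict <- trim_tag(reads, tag, max_mismatch = 0)
  expect_identical(strict$trimmed$read_id, "r1")
  expect_true("r3" %in% strict$rejected$read_id)

  # conservation + never longer than input
  expect_equal(nrow(out$trimmed) + nrow(out$rejected), nrow(reads))
  expect_true(all(out$trimmed$flank_length <=
                    nchar(reads$seq[match(out$trimmed$read_id,
                                          reads$read_id)])))
})

test_that("trim_tag rejects short flanks and truncates concatemers", {
  short <- data.frame(read_id = "s", seq = paste0(tag, "ACGTACGT"))
  expect_identical(trim_tag(short, tag)$rejected$reason, "too_short")

  flank1 <- strrep("GATC", 10)
  conc <- data.frame(read_id = "c",
                     seq = paste0(tag, flank1, tag, strrep("TTAA", 10)))
  out <- trim_tag(conc, tag)
  expect_identical(out$trimmed$flank, flank1)
  expect_true(out$trimmed$concatemer)
})

test_that("map_flank places unique flanks and computes junctions", {
  set.seed(42)
  chr <- paste0(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrM = chr))
  flank <- substr(chr, 1001, 1040)  # unique 40-mer, 0-based start 1000
  tr <- data.frame(read_id = "f1", flank = flank, flank_length = 40L)
  out <- map_flank(tr, genome)
  aln <- out$alignments
  expect_equal(nrow(aln), 1)
  expect_identical(aln$strand, "+")
  expect_equal(aln$start, 1000L)
  expect_equal(aln$junction_pos, 1000L)
  expect_equal(aln$mismatches, 0L)

  # reverse-complemented flank maps to the minus strand, junction at the
  # interval's last base; re-extracting the sequence closes the loop
  rcf <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(flank)))
  out2 <- map_flank(data.frame(read_id = "f2", flank = rcf,
                               flank_length = 40L), genome)
  a2 <- out2$alignments
  expect_identical(a2$strand, "-")
  expect_equal(a2$start, 1000L)
  expect_equal(a2$junction_pos, a2$end - 1L)
  expect_identical(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, a2$start + 1, a2$end)))), rcf)

  # a flank planted at two loci is multimapped
  chr2 <- paste0(chr, strrep("N", 10), flank)
  out3 <- map_flank(data.frame(read_id = "f3", flank = flank,
                               flank_length = 40L),
                    Biostrings::DNAStringSet(c(chrM = chr2)))
  expect_identical(out3$rejected$reason, "multimapped")

  # absent sequence is unmapped
  out4 <- map_flank(data.frame(read_id = "f4",
                               flank = strrep("ACCGGTTA", 5),
                               flank_length = 40L), genome)
  expect_identical(out4$rejected$reason, "unmapped")

  expect_error(map_flank(data.frame(read_id = "f5",
                                    flank = paste0(substr(flank, 1, 38),
                                                   "XX"),
                                    flank_length = 40L), genome),
               "non-ACGTN")
})

test_that("built-in mapper agrees with a brute-force genome scan", {
  run <- get_sim_run()
  genome <- run$reference$genome
  set.seed(99)
  n <- 250
  chroms <- sample(names(genome), n, replace = TRUE,
                   prob = Biostrings::width(genome))
  lens <- sample(30:120, n, replace = TRUE)
  flanks <- vapply(seq_len(n), function(i) {
    L <- Biostrings::width(genome)[match(chroms[i], names(genome))]
    s <- sample(L - lens[i], 1)
    fl <- as.character(genome[[chroms[i]]][s:(s + lens[i] - 1)])
    if (runif(1) < 0.5) fl <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fl)))
    fl
  }, character(1))
  tr <- data.frame(read_id = sprintf("r%03d", seq_len(n)), flank = flanks,
                   flank_length = nchar(flanks), stringsAsFactors = FALSE)
  got <- map_flank(tr, genome)
  for (i in seq_len(n)) {
    oracle <- brute_force_map(flanks[i], genome)
    if (oracle$status == "mapped") {
      row <- got$alignments[got$alignments$read_id == tr$read_id[i], ]
      expect_equal(nrow(row), 1)
      expect_identical(row$chrom, oracle$chrom)
      expect_identical(row$strand, oracle$strand)
      expect_equal(row$start, oracle$start)
      expect_equal(row$junction_pos, oracle$junction)
    } else {
      rej <- got$rejected[got$rejected$read_id == tr$read_id[i], ]
      expect_identical(rej$reason, oracle$status)
    }
  }
})

test_that("alignments round-trip through BED6", {
  run <- get_sim_run()
  reads <- run$reads[run$reads$arm == "experimental" &
                       run$reads$replicate == "A", ][1:200, ]
  tr <- trim_tag(data.frame(read_id = reads$read_id, seq = reads$seq))
  mp <- map_flank(tr$trimmed, run$reference$genome)
  bed <- tempfile(fileext = ".bed")
  export_alignments_bed(mp$alignments, bed)
  back <- import_alignments(bed, arm = "experimental", replicate = "A")
  cols <- c("read_id", "chrom", "start", "end", "strand", "junction_pos",
            "flank_length", "mismatches")
  expect_equal(back[, cols], mp$alignments[, cols])
})

test_that("import_alignments derives junctions from BED and SAM", {
  bed <- tempfile(fileext = ".bed")
  file.create(bed)
  expect_equal(nrow(import_alignments(bed, arm = "x", replicate = "A")), 0)

  writeLines("chr1\t100\t160\tread7\t0\t-", bed)
  a <- import_alignments(bed, arm = "experimental", replicate = "B")
  expect_equal(a$junction_pos, 159L)
  expect_equal(a$flank_length, 60L)
  expect_identical(a$replicate, "B")

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t160", bad)
  expect_error(import_alignments(bad, arm = "x", replicate = "A"),
               "strand")

  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t0\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t201\t60\t20M5D30M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r4\t256\tchr1\t301\t60\t50M\t*\t0\t0\t*\t*"), sam)
  s <- import_alignments(sam, arm = "experimental", replicate = "A")
  expect_identical(s$read_id, c("r1", "r2"))
  expect_equal(s$start, c(100L, 200L))
  expect_equal(s$flank_length, c(50L, 55L))   # CIGAR reference span
  expect_identical(s$strand, c("+", "-"))
  expect_equal(s$junction_pos, c(100L, 254L))
})

test_that("error-free simulated reads recover planted junctions", {
  cfg <- sim_config(seed = 31, base_error_rate = 0, dup_mean = 1)
  ref <- generate_reference(cfg)
  ev <- sample_insertions(ref, cfg)
  sim <- simulate_reads(ref, ev, cfg)
  sub <- sim$reads[sim$reads$replicate == "A" &
                     sim$reads$arm == "experimental", ]
  tr <- trim_tag(data.frame(read_id = sub$read_id, seq = sub$seq))
  expect_equal(nrow(tr$trimmed), nrow(sub))
  mp <- map_flank(tr$trimmed, ref$genome)
  expect_equal(nrow(mp$rejected), 0)
  truth_j <- sub$junction[match(mp$alignments$read_id, sub$read_id)]
  expect_true(all(mp$alignments$junction_pos == truth_j))
  truth_o <- sub$orientation[match(mp$alignments$read_id, sub$read_id)]
  expect_true(all(mp$alignments$strand == truth_o))
})
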
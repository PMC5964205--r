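#' @importFrom stats median rbinom rpois runif setNames aggregate cor
#' @importFrom utils read.delim write.table head
NULL

# Statistical mode of an integer vector; ties broken toward the smallest value.
stat_mode <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

# Hamming distance between two equal-length raw vectors.
raw_mismatches <- function(a, b) sum(a != b)

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorised Hamming distance between the length-nchar(tag) prefix of `seqs`
# and `tag`. Positions beyond a sequence's end count as mismatches.
prefix_mismatches <- function(seqs, tag) {
  n <- nchar(tag)
  mm <- integer(length(seqs))
  for (i in seq_len(n)) {
    ci <- substr(seqs, i, i)
    mm <- mm + (ci != substr(tag, i, i))
  }
  mm
}

#' Write reads to a FASTQ file
#'
#' Four-line FASTQ records with Sanger-encoded qualities. Used by the
#' simulator; constant quality strings are written because downstream
#' processing operates on mapped coordinates and fragment lengths, not
#' base qualities.
#'
#' @param ids character vector of read identifiers.
#' @param seqs character vector of read sequences.
#' @param path output file path.
#' @param qual_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path, qual_char = "I") {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) == 0) {
    file.create(path)
    return(invisible(path))
  }
  quals <- vapply(nchar(seqs), function(n) strrep(qual_char, n), character(1))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n", quals)
  writeLines(rec, path)
  invisible(path)
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  if (file.info(path)$size == 0) {
    return(data.frame(read_id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}
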
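mk_aln <- function(chrom, start, end, arm = "experimental",
                   replicate = "A", strand = "+") {
  n <- length(start)
  data.frame(read_id = sprintf("r%d", seq_len(n)), chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand,
             junction_pos = ifelse(strand == "+", as.integer(start),
                                   as.integer(end) - 1L),
             flank_length = as.integer(end - start), mismatches = 0L,
             arm = arm, replicate = replicate, stringsAsFactors = FALSE)
}

test_that("master blocks merge overlap across all samples jointly", {
  aln <- mk_aln("chr1", c(100, 500), c(200, 600))
  out <- build_master_blocks(aln)
  expect_equal(nrow(out$blocks), 2)

  # A and B only overlap via a long read in C: one joint block
  aln3 <- rbind(mk_aln("chr1", 100, 150, replicate = "A"),
                mk_aln("chr1", 220, 280, replicate = "B"),
                mk_aln("chr1", 140, 240, replicate = "C"))
  out3 <- build_master_blocks(aln3)
  expect_equal(nrow(out3$blocks), 1)
  expect_equal(out3$blocks$start, 100L)
  expect_equal(out3$blocks$end, 280L)

  # bookended intervals do not overlap and stay separate
  ab <- build_master_blocks(mk_aln("chr1", c(100, 200), c(200, 300)))
  expect_equal(nrow(ab$blocks), 2)
})

test_that("master blocks equal the pairwise overlap-closure oracle", {
  set.seed(17)
  n <- 1000
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  start <- sample(50000, n, replace = TRUE)
  end <- start + sample(20:400, n, replace = TRUE)
  aln <- mk_aln(chrom, start, end)
  out <- build_master_blocks(aln)
  oracle <- overlap_closure_groups(chrom, start, end)
  # identical partitions: block assignment refines to the same groups
  expect_equal(length(unique(out$alignments$block_id)),
               length(unique(oracle)))
  tab <- table(out$alignments$block_id, oracle)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # partition property: members sum to total
  expect_equal(sum(out$blocks$n_members), n)
  # block interval is the bounding union of its members
  agg_min <- tapply(out$alignments$start, out$alignments$block_id, min)
  agg_max <- tapply(out$alignments$end, out$alignments$block_id, max)
  expect_equal(as.vector(agg_min[out$blocks$block_id]), out$blocks$start)
  expect_equal(as.vector(agg_max[out$blocks$block_id]), out$blocks$end)
})

test_that("block construction is order invariant", {
  set.seed(23)
  aln <- mk_aln("chr1", s <- sample(5000, 200, TRUE), s + 50)
  a <- build_master_blocks(aln)
  perm <- sample(nrow(aln))
  b <- build_master_blocks(aln[perm, ])
  expect_equal(a$blocks, b$blocks)
  expect_identical(a$alignments$block_id[perm], b$alignments$block_id)
})

test_that("unique-length dedup is a set-cardinality count", {
  aln <- mk_aln("chr1", rep(1000, 5), 1000 + c(40, 40, 55, 70, 70))
  aln <- build_master_blocks(aln)$alignments
  d <- dedup_unique_lengths(aln)
  expect_equal(d$A, 3L)
  expect_equal(d$pooled, 3L)

  same <- mk_aln("chr1", rep(1000, 4), rep(1060, 4))
  expect_equal(dedup_unique_lengths(
    build_master_blocks(same)$alignments)$A, 1L)

  # idempotence under exact duplication
  dup <- rbind(aln, aln[1, ])
  expect_equal(dedup_unique_lengths(dup)$A, d$A)

  # pooled is the union over replicates
  two <- rbind(mk_aln("chr1", rep(1000, 2), 1000 + c(40, 55),
                      replicate = "A"),
               mk_aln("chr1", rep(1000, 2), 1000 + c(55, 70),
                      replicate = "B"))
  two <- build_master_blocks(two)$alignments
  dd <- dedup_unique_lengths(two)
  expect_equal(dd[, c("A", "B", "C")], data.frame(A = 2L, B = 2L, C = 0L),
               ignore_attr = TRUE)
  expect_equal(dd$pooled, 3L)
})

test_that("dedup counts are invariant under PCR duplication factor", {
  cfg1 <- sim_config(seed = 41, base_error_rate = 0, dup_mean = 1)
  cfg10 <- sim_config(seed = 41, base_error_rate = 0, dup_mean = 10)
  ref <- generate_reference(cfg1)
  ev <- sample_insertions(ref, cfg1)
  s1 <- call_sites_from_truth(simulate_reads(ref, ev, cfg1)$reads)
  s10 <- call_sites_from_truth(simulate_reads(ref, ev, cfg10)$reads)
  key <- function(s) paste(s$block_id, s$arm)
  expect_identical(key(s1), key(s10))
  expect_equal(s1[, c("A", "B", "C", "pooled")],
               s10[, c("A", "B", "C", "pooled")])
})

test_that("call_sites reports junctions, medians and stack checks", {
  # one clean pyramidal site
  aln <- rbind(mk_aln("chr1", rep(1000, 3), 1000 + c(40, 55, 70),
                      replicate = "A"),
               mk_aln("chr1", rep(1000, 3), 1000 + c(40, 60, 80),
                      replicate = "B"),
               mk_aln("chr1", rep(1000, 4), 1000 + c(40, 50, 60, 70),
                      replicate = "C"))
  sc <- call_sites(build_master_blocks(aln))
  expect_equal(nrow(sc), 1)
  expect_equal(sc$junction_pos, 1000L)
  expect_true(sc$stack_ok)
  expect_equal(sc$median_read_sample, 3)
  expect_equal(sc$pooled, 6L)  # lengths {40,50,55,60,70,80}

  # median is the middle order statistic of the three replicate counts
  expect_equal(median(c(50, 48, 53)), 50)

  # two junctions 500 bp apart in one block: no shared stack
  spread <- mk_aln("chr1", c(1000, 1500), c(1600, 1650))
  sc2 <- call_sites(build_master_blocks(spread))
  expect_false(sc2$stack_ok)

  # simulated site, error-free: junction equals the planted coordinate
  cfg <- sim_config(seed = 43, base_error_rate = 0)
  ref <- generate_reference(cfg)
  ev <- sample_insertions(ref, cfg)
  sc3 <- call_sites_from_truth(simulate_reads(ref, ev, cfg)$reads)
  exp3 <- sc3[sc3$arm == "experimental", ]
  m <- match(paste(exp3$chrom, exp3$junction_pos),
             paste(ev$chrom, ev$pos))
  expect_false(any(is.na(m)))
  expect_true(all(exp3$stack_ok[exp3$pooled >= 3]))
  expect_true(all(exp3$strand == ev$orientation[m]))
})

test_that("replicate concordance matches definitional rank correlation", {
  s <- data.frame(A = c(1, 2, 3, 4), B = c(2, 4, 6, 9), C = c(1, 2, 3, 4))
  rho <- replicate_concordance(s)
  expect_equal(unname(rho["AB"]), 1.0)
  expect_equal(unname(rho["AC"]), 1.0)

  s2 <- data.frame(A = c(3, 1, 2), B = c(2, 3, 1), C = c(3, 1, 2))
  rho2 <- replicate_concordance(s2)
  # definitional check: covariance of ranks over product of sds
  ra <- rank(s2$A); rb <- rank(s2$B)
  expect_equal(unname(rho2["AB"]),
               sum((ra - mean(ra)) * (rb - mean(rb))) /
                 sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2)))
  expect_equal(unname(rho2["AB"]), -0.5)

  expect_true(all(is.na(replicate_concordance(
    data.frame(A = 1:2, B = 1:2, C = 1:2)))))
})
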
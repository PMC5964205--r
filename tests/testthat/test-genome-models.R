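test_that("read_genome handles empty files, case and names", {
  f <- tempfile(fileext = ".fa")
  file.create(f)
  expect_length(read_genome(f), 0)

  writeLines(c(">chrA description here", "acgtACGTnn", ">chrB", "GGGCCC"), f)
  g <- read_genome(f)
  expect_identical(names(g), c("chrA", "chrB"))
  expect_identical(as.character(g[["chrA"]]), "ACGTACGTNN")
  expect_identical(Biostrings::width(g), c(10L, 6L))

  expect_error(read_genome(tempfile()), "not found")
})

test_that("read_genome round-trips the simulator reference", {
  run <- get_sim_run()
  g <- read_genome(run$fasta)
  expect_identical(names(g), names(run$reference$genome))
  expect_identical(Biostrings::width(g),
                   Biostrings::width(run$reference$genome))
})

test_that("read_annotation parses GTF into gene models", {
  f <- tempfile(fileext = ".gtf")
  file.create(f)
  expect_equal(nrow(read_annotation(f)$genes), 0)

  run <- get_sim_run()
  ann <- read_annotation(run$gtf)
  man <- read.delim(run$gene_manifest, stringsAsFactors = FALSE)
  expect_equal(nrow(ann$genes), nrow(man))
  # exon counts and protein lengths must match the generator's manifest
  for (i in seq_len(nrow(man))) {
    tx <- ann$transcripts[ann$transcripts$gene_id == man$gene_id[i], ]
    expect_equal(tx$n_exons, man$n_exons[i])
    expect_equal(tx$protein_length_aa, man$protein_length_aa[i])
    expect_true(tx$cds_complete)
  }
  # exon coordinate agreement with the in-memory truth structure
  truth <- run$reference$annotation$exons
  got <- ann$exons[order(ann$exons$transcript_id, ann$exons$start),
                   c("transcript_id", "start", "end", "exon_rank")]
  want <- truth[order(truth$transcript_id, truth$start),
                c("transcript_id", "start", "end", "exon_rank")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("read_annotation keeps stable gene identifiers", {
  f <- tempfile(fileext = ".gtf")
  writeLines(paste0(
    'chr18\tsrc\texon\t100\t200\t.\t+\t.\t',
    'gene_id "ENSG00000134030"; transcript_id "T1"; gene_name "CTIF";'), f)
  ann <- read_annotation(f)
  expect_identical(ann$genes$gene_id, "ENSG00000134030")
  expect_identical(ann$genes$gene_name, "CTIF")
})

test_that("read_annotation reports structural errors", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t1\t50\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T\";",
               "chr1\tsrc\texon\t100\t200\t.\t+\t.\ttranscript_id \"T\";"), f)
  expect_error(read_annotation(f), "line 2")

  f2 <- tempfile(fileext = ".gtf")
  writeLines(c('chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "G1"; transcript_id "T";',
               'chr1\tsrc\texon\t50\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T";'),
             f2)
  expect_error(read_annotation(f2), "overlapping exons")
})

test_that("intron_phase equals the modular sum of upstream coding bases", {
  ann <- toy_annotation()
  # geneA upstream CDS per exon: 100, 47, 120, 90 nt
  expect_equal(intron_phase(ann, "GA.t1", 1), 100 %% 3)   # 1
  expect_equal(intron_phase(ann, "GA.t1", 2), 147 %% 3)   # 0
  expect_equal(intron_phase(ann, "GA.t1", 3), 267 %% 3)   # 0
  expect_equal(intron_phase(ann, "GA.t1", 4), 357 %% 3)   # 0
  # a 300-nt single upstream exon would be phase 0; covered by index 2+
  # UTR intron: no coding base upstream -> undefined
  expect_true(is.na(intron_phase(ann, "GB.t1", 1)))
  expect_equal(intron_phase(ann, "GB.t1", 2), 150 %% 3)
  expect_error(intron_phase(ann, "GA.t1", 5), "out of range")
  expect_error(intron_phase(ann, "GA.t1", 0), "out of range")
})

test_that("locate_insertion classifies sites and sums upstream CDS", {
  ann <- toy_annotation()
  expect_identical(locate_insertion(ann, "chrT", 1500L, "+")$status,
                   "intergenic")
  expect_identical(locate_insertion(ann, "chrT", 120L, "+")$status,
                   "exonic")
  ctx <- locate_insertion(ann, "chrT", 650L, "+")  # intron 3 of geneA
  expect_identical(ctx$status, "intronic")
  expect_equal(ctx$intron_index, 3L)
  expect_equal(ctx$upstream_cds_nt, 100L + 47L + 120L)
  expect_true(ctx$orientation_match)
  # same site, anti-oriented: gene still found, orientation flagged
  ctx2 <- locate_insertion(ann, "chrT", 650L, "-")
  expect_false(ctx2$orientation_match)
  # minus-strand gene: intron between rank-2 and rank-3 exons
  ctx3 <- locate_insertion(ann, "chrT", 2200L, "-")
  expect_identical(ctx3$status, "intronic")
  expect_equal(ctx3$intron_index, 2L)
  expect_equal(ctx3$upstream_cds_nt, 150L)
  expect_error(locate_insertion(ann, "chrZ", 10L, "+"), "absent")
})

test_that("predict_fusion applies the frame-variant and truncation rules", {
  ann <- toy_annotation()
  inter <- predict_fusion(locate_insertion(ann, "chrT", 1500L, "+"))
  expect_false(inter$viable)
  expect_length(inter$matching_variants, 0)
  expect_equal(inter$truncation_aa, 0L)

  # intron 1 of geneA: phase 1 -> variant 2 complements; 100 nt -> 33 aa
  fp <- predict_fusion(locate_insertion(ann, "chrT", 300L, "+"))
  expect_true(fp$viable)
  expect_identical(fp$matching_variants, 2L)
  expect_equal(fp$truncation_aa, 33L)

  # strict mode: requiring the wrong variant kills viability
  expect_false(predict_fusion(locate_insertion(ann, "chrT", 300L, "+"),
                              variant = 0)$viable)
  expect_true(predict_fusion(locate_insertion(ann, "chrT", 300L, "+"),
                             variant = 2)$viable)

  # anti-oriented intronic site is not viable
  expect_false(predict_fusion(locate_insertion(ann, "chrT", 300L, "-"))$viable)
  # 5' UTR intron (geneB intron 1, genomic [2450,2600)): no fusion
  expect_false(predict_fusion(locate_insertion(ann, "chrT", 2500L, "-"))$viable)

  expect_error(predict_fusion(list()), "undefined")
})

test_that("predict_fusion is deterministic and truncation non-decreasing", {
  ann <- toy_annotation()
  ctx <- locate_insertion(ann, "chrT", 650L, "+")
  expect_identical(predict_fusion(ctx), predict_fusion(ctx))
  # over geneA introns: exactly one matching variant each, and
  # truncation_aa non-decreasing with intron index
  upstream <- cumsum(c(100, 47, 120, 90))
  trunc <- integer(4)
  for (i in 1:4) {
    pos <- c(300L, 450L, 650L, 800L)[i]
    fp <- predict_fusion(locate_insertion(ann, "chrT", pos, "+"))
    expect_length(fp$matching_variants, 1)
    expect_equal(fp$matching_variants, (3 - upstream[i] %% 3) %% 3)
    trunc[i] <- fp$truncation_aa
    expect_equal(trunc[i], upstream[i] %/% 3)
  }
  expect_true(all(diff(trunc) >= 0))
})

test_that("viable fusions translate in frame with the reporter tag", {
  run <- get_sim_run()
  ann <- run$reference$annotation
  genome <- run$reference$genome
  ev <- run$events[run$events$event_class == "true_trap", ][1:8, ]
  for (i in seq_len(nrow(ev))) {
    ctx <- locate_insertion(ann, ev$chrom[i], ev$pos[i], ev$orientation[i])
    fp <- predict_fusion(ctx)
    expect_true(fp$viable)
    prot <- fusion_translation(ann, genome, ctx$transcript_id,
                               ctx$intron_index, fp$matching_variants)
    native <- native_protein(ann, genome, ctx$transcript_id)
    # retained N-terminus equals the native prefix
    expect_identical(substr(prot, 1, fp$truncation_aa),
                     substr(native, 1, fp$truncation_aa))
    # reporter tag lands in frame only for the matching variant
    expect_true(grepl("YPYDVPDYA", prot, fixed = TRUE))
    off <- (fp$matching_variants + 1) %% 3
    expect_false(grepl("YPYDVPDYA",
                       fusion_translation(ann, genome, ctx$transcript_id,
                                          ctx$intron_index, off),
                       fixed = TRUE))
  }
})
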
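# Readers, writers, domain-type invariants and coordinate conventions.

test_that("VCF ingestion maps dialect INFO keys and handles ALT expansion", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=CASE,Number=1,Type=String,Description="case">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="gene">',
    '##INFO=<ID=HGVSC,Number=1,Type=String,Description="hgvs">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="csq">',
    '##INFO=<ID=ZYG,Number=1,Type=String,Description="zyg">',
    '##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description="af">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste("chr10", "85001000", ".", "G", "A", ".", "PASS",
          "CASE=Pt-7;GENE=CDHR1;HGVSC=c.783G>A;CSQ=ncss;ZYG=hom;AF_GNOMAD=0.003052",
          sep = "\t")), path)
  v <- read_variants(path)
  expect_equal(nrow(v), 1L)
  expect_equal(v$af_gnomad, 0.003052)
  expect_equal(v$gene, "CDHR1")
  # unannotated scores stay NA, never zero
  expect_true(is.na(v$phylop) && is.na(v$cadd_phred) && is.na(v$sai_ag))
})

test_that("an empty VCF with a valid header yields an empty record list", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), path)
  v <- suppressWarnings(read_variants(path))
  expect_equal(nrow(v), 0L)
})

test_that("TSV and VCF ingestion of equivalent content give identical records", {
  fx <- build_cohort_fixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants(fx$variants, tsv, format = "tsv")
  write_variants(fx$variants, vcf, format = "vcf")
  a <- read_variants(tsv)
  b <- read_variants(vcf)
  key <- function(d) d[order(d$case_id, d$gene, d$hgvs_c, d$zygosity), ]
  a <- key(a); b <- key(b)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  # and both reproduce the in-memory records field-for-field
  o <- key(fx$variants); rownames(o) <- NULL
  expect_equal(a, o)
})

test_that("reader errors name the offending record and list the vocabulary", {
  df <- tiny_variant()
  df$consequence <- "stopgain"
  expect_error(validate_variants(df), "accepted vocabulary")
  bad <- tiny_variant()
  bad$pos <- -5L
  expect_error(validate_variants(bad), "pos")
  # prior allele without classification violates the record contract
  p <- tiny_variant()
  p$prior_allele <- TRUE
  expect_error(validate_variants(p), "classification")
})

test_that("score and frequency ranges are enforced on ingestion", {
  v <- tiny_variant()
  v$af_gnomad <- 1.2
  expect_error(validate_variants(v), "\\[0, 1\\]")
  v2 <- tiny_variant()
  v2$cadd_phred <- 120
  expect_error(validate_variants(v2), "cadd")
})

test_that("BED panel coordinates convert 0-based half-open to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "#chrom\tstart\tend\tgene\tpanel\tinheritance\tpromoter_start\tpromoter_end\texon_starts\texon_ends",
    "chr19\t54106453\t54133135\tPRPF31\tird\tAD_incomplete_penetrance\t.\t.\t54110000\t54110120"),
    path)
  p <- read_panel(path)
  expect_equal(p$start, 54106454L)  # BED off-by-one forced
  expect_equal(p$end, 54133135L)
  expect_equal(p$exons[[1]]$start, 54110001L)
  # round trip is an exact bijection
  out <- withr::local_tempfile(fileext = ".bed")
  write_panel(p, out)
  p2 <- read_panel(out)
  expect_equal(p2, p)
})

test_that("degenerate and duplicate panel intervals are rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t100\tG1\tird\tAR\t.\t.\t.\t."), path)
  expect_error(read_panel(path), "zero-length")
  dup <- rbind(tiny_panel()[1, ], tiny_panel()[1, ])
  dup$exons <- list(tiny_panel()$exons[[1]], tiny_panel()$exons[[1]])
  expect_error(validate_panel(dup), "overlapping duplicate")
})

test_that("concatenating two panels preserves the panel field as a union", {
  a <- tiny_panel()
  b <- a
  b$gene <- c("CIL1", "CIL2")
  b$chrom <- c("chr7", "chr8")
  b$panel <- "ciliopathy"
  u <- validate_panel(rbind(a, b))
  expect_equal(nrow(u), 4L)
  expect_setequal(unique(u$panel), c("ird", "ciliopathy"))
})

test_that("cohort round trip through the file formats is lossless", {
  fx <- build_cohort_fixture()
  dir <- withr::local_tempdir()
  write_cohort(fx, dir, variant_format = "vcf")
  fx2 <- read_cohort(dir)
  key <- function(d) {
    d <- d[order(d$case_id, d$gene, d$hgvs_c, d$zygosity), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(fx2$variants), key(fx$variants))
  expect_equal(fx2$cases, fx$cases, ignore_attr = TRUE)
  expect_equal(fx2$svs, fx$svs, ignore_attr = TRUE)
  expect_equal(fx2$repeats, fx$repeats, ignore_attr = TRUE)
  expect_equal(fx2$assay_bands, fx$assay_bands, ignore_attr = TRUE)
  expect_equal(fx2$panel$start, fx$panel$start)
  expect_equal(fx2$panel$exons, fx$panel$exons, ignore_attr = TRUE)
})

test_that("case reports carry exactly the causal alleles of the genotype", {
  fx <- build_cohort_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  r23 <- resolve_case(fx, "Pt-23")
  write_case_report(r23, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$status, "solved")
  expect_equal(rep$causal_gene, "PRPF31")
  expect_true(grepl("del", rep$causal_alleles$allele[1]))
  # unsolved case: empty causal fields
  path2 <- withr::local_tempfile(fileext = ".json")
  r27 <- resolve_case(fx, "Pt-27")
  write_case_report(r27, path2)
  rep2 <- jsonlite::read_json(path2, simplifyVector = TRUE)
  expect_equal(rep2$status, "unsolved")
  expect_null(rep2$causal_gene)
  expect_equal(length(rep2$causal_alleles), 0L)
})
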
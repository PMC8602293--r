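# Structural-variant and repeat-expansion interpretation.

test_that("SV length uses inclusive coordinates", {
  expect_equal(sv_length(54106454, 54133135), 26682L)
  expect_equal(round(sv_length(54106454, 54133135) / 1000, 2), 26.68)
  expect_equal(sv_length(100, 100), 1L)
  expect_error(sv_length(10, 5), ">=")
})

test_that("SV length equals the count of integers in the interval and is additive", {
  set.seed(21)
  for (i in 1:50) {
    s <- sample(1e6, 1)
    e <- s + sample(0:5000, 1)
    expect_equal(sv_length(s, e), length(s:e))
    if (e > s) {
      m <- sample(s:(e - 1), 1)
      expect_equal(sv_length(s, m) + sv_length(m + 1, e), sv_length(s, e))
    }
  }
})

test_that("microhomology finds the 12-bp constructed junction", {
  mh <- "ACGTACGTACGT"
  res <- microhomology(paste0("TT", mh), paste0(mh, "GG"))
  expect_equal(res$length, 12L)
  expect_equal(res$sequence, mh)
  expect_equal(microhomology("AAAA", "CCCC")$length, 0L)
  expect_equal(microhomology("AAAA", "CCCC")$sequence, "")
})

test_that("N never matches and non-DNA characters error", {
  expect_equal(microhomology("AANN", "NNCC")$length, 0L)
  expect_error(microhomology("ACGU", "ACGT"), "DNA")
  expect_error(microhomology("", "ACGT"), "nonempty")
})

test_that("microhomology matches the exhaustive oracle on random flanks", {
  set.seed(5)
  for (i in 1:200) {
    l <- rand_dna(sample(1:30, 1))
    r <- rand_dna(sample(1:30, 1))
    # force shared junctions in half the draws
    if (i %% 2 == 0) {
      k <- sample(1:10, 1)
      shared <- rand_dna(k)
      l <- paste0(l, shared); r <- paste0(shared, r)
    }
    expect_equal(microhomology(l, r)$length, microhomology_oracle(l, r))
  }
})

test_that("microhomology length is invariant under joint reverse-complement", {
  set.seed(13)
  for (i in 1:50) {
    shared <- rand_dna(sample(2:12, 1))
    l <- paste0(rand_dna(8), shared)
    r <- paste0(shared, rand_dna(8))
    fwd <- microhomology(l, r)$length
    rev <- microhomology(revcomp(r), revcomp(l))$length
    expect_equal(fwd, rev)
  }
})

test_that("gene disruption classes match the chromosome-19 deletion", {
  fx <- build_cohort_fixture()
  sv <- fx$svs[fx$svs$case_id == "Pt-23", ]
  hits <- genes_disrupted(sv, fx$panel)
  expect_equal(hits$consequence[hits$gene == "PRPF31"], "whole_gene")
  expect_equal(hits$consequence[hits$gene == "TFPT"], "whole_gene")
  expect_equal(hits$consequence[hits$gene == "NDUFA3"], "promoter_only")
  expect_equal(sv_length(sv$start, sv$end), 26682L)
})

test_that("a single-exon deletion of 101 coding bases is a frameshift", {
  fx <- build_cohort_fixture()
  sv <- fx$svs[fx$svs$case_id == "Pt-22", ]
  itp <- interpret_sv(sv, fx$panel)
  hit <- itp$genes_hit[itp$genes_hit$gene == "RPGRIP1", ]
  expect_equal(hit$consequence, "single_exon")
  expect_equal(hit$deleted_coding_bp, 101L)
  expect_equal(itp$frame_effect, "frameshift")
  expect_equal(itp$microhomology_len, 12L)
})

test_that("a deletion strictly inside one intron is intronic_only", {
  panel <- tiny_panel()
  sv <- validate_svs(data.frame(case_id = "T-1", chrom = "chr1",
                                start = 3000L, end = 4000L,
                                svtype = "del", zygosity = "het"))
  hits <- genes_disrupted(sv, panel)
  expect_equal(hits$consequence[hits$gene == "GENE1"], "intronic_only")
})

test_that("in-frame multi-exon deletions are recognized", {
  panel <- tiny_panel()
  # GENE1 exons: 101 + 104 + 101 bp; first two = 205 (frameshift),
  # a deletion covering only the 104-bp second exon is not in frame either;
  # cover exon 1 and 2 -> 205 %% 3 == 1 -> frameshift
  sv <- validate_svs(data.frame(case_id = "T-1", chrom = "chr1",
                                start = 1500L, end = 7000L,
                                svtype = "del", zygosity = "het"))
  itp <- interpret_sv(sv, panel)
  expect_equal(itp$genes_hit$consequence[itp$genes_hit$gene == "GENE1"],
               "multi_exon")
  expect_equal(itp$frame_effect, "frameshift")
})

test_that("repeat classification partitions all counts into three classes", {
  rng <- default_repeat_ranges()
  expect_equal(classify_repeat("ATXN7", 70, rng)$class,
               "pathogenic_expansion")
  expect_equal(classify_repeat("ATXN7", 10, rng)$class, "normal")
  expect_equal(classify_repeat("ATXN7", 25, rng)$class, "indeterminate")
  # exhaustive partition: every count gets exactly one class
  cls <- classify_repeat("ATXN7", 1:500, rng)$class
  expect_true(all(cls %in% c("normal", "indeterminate",
                             "pathogenic_expansion")))
  expect_equal(sum(cls == "normal"), 19 - 3 + 1)
  expect_equal(sum(cls == "pathogenic_expansion"), 460 - 37 + 1)
  expect_error(classify_repeat("HTT", 50, rng), "unknown repeat locus")
})
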
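# Splice-assay quantification and interpretation.

test_that("fragment quantification normalizes intensities to percent", {
  q <- quantify_fragments(c(332, 225), c(78.9, 21.1))
  expect_equal(q$percent, c(78.9, 21.1))
  expect_equal(quantify_fragments(c(400, 300), c(3, 1))$percent, c(75, 25))
  expect_equal(quantify_fragments(500, 7)$percent, 100)
  expect_equal(sum(q$percent), 100, tolerance = 1e-9)
  expect_error(quantify_fragments(c(100, 200), c(0, 0)), "positive")
})

test_that("quantification is invariant to rescaling all intensities", {
  set.seed(31)
  for (i in 1:20) {
    ints <- stats::runif(4, 0.1, 50)
    a <- quantify_fragments(1:4 * 100, ints)$percent
    b <- quantify_fragments(1:4 * 100, ints * stats::runif(1, 0.01, 90))$percent
    expect_equal(a, b)
  }
})

test_that("expected fragment lengths follow the event arithmetic", {
  expect_equal(predict_fragment_length(225, splice_event("exon_elongation", 107)),
               332L)
  expect_equal(predict_fragment_length(274, splice_event("pseudoexon_insertion", 104)),
               378L)
  expect_equal(predict_fragment_length(492, splice_event("pseudoexon_insertion", 75)),
               567L)
  expect_equal(predict_fragment_length(500, splice_event("exon_skipping", 144)),
               356L)
  expect_error(predict_fragment_length(100, splice_event("exon_skipping", 150)),
               "smaller")
})

test_that("inserting then skipping the same size is the identity", {
  set.seed(17)
  for (i in 1:25) {
    wt <- sample(100:800, 1)
    k <- sample(1:99, 1)
    up <- predict_fragment_length(wt, splice_event("pseudoexon_insertion", k))
    expect_equal(predict_fragment_length(up, splice_event("exon_skipping", k)),
                 wt)
  }
})

test_that("splice events derive frame from size", {
  expect_equal(splice_event("pseudoexon_insertion", 75)$frame, "in_frame")
  expect_equal(splice_event("pseudoexon_insertion", 104)$frame, "frameshift")
  expect_error(splice_event("intron_retention", 10), "kind")
  expect_error(splice_event("exon_skipping", 0), "positive")
})

test_that("normalization reproduces the published rounding convention", {
  expect_equal(normalized_wt_percent(42.0, 46.0), 91.0)
  expect_equal(normalized_wt_percent(50, 100), 50.0)
  expect_equal(normalized_wt_percent(0, 76.0), 0.0)
  expect_equal(normalized_wt_percent(120, 100), 100)  # capped
  expect_error(normalized_wt_percent(10, 0), "positive")
})

test_that("severity classification uses the <25% severe cut and is monotone", {
  expect_equal(classify_allele_severity(21.1), "severe")
  expect_equal(classify_allele_severity(91.0), "mild")
  expect_equal(classify_allele_severity(50), "moderate")
  expect_equal(classify_allele_severity(24.999), "severe")
  expect_equal(classify_allele_severity(25), "moderate")
  expect_equal(classify_allele_severity(75), "mild")
  sev_rank <- c(severe = 1, moderate = 2, mild = 3)
  grid <- seq(0, 100, by = 0.5)
  r <- sev_rank[vapply(grid, classify_allele_severity, character(1))]
  expect_true(all(diff(r) >= 0))
  expect_error(classify_allele_severity(120), "\\[0, 100\\]")
})

test_that("a mutant construct losing all wild-type product is severe", {
  fx <- build_cohort_fixture()
  eys <- interpret_assay(
    fx$assay_bands[fx$assay_bands$gene == "EYS", ], 274)
  expect_true(eys$defect_present)
  expect_equal(eys$pct_wt_raw, 0)
  expect_equal(eys$severity, "severe")
})

test_that("mutant lanes matching the wild-type construct mean no defect", {
  fx <- build_cohort_fixture()
  nd <- interpret_assay(
    fx$assay_bands[fx$assay_bands$hgvs_c == "c.6148-89G>A", ], 410)
  expect_false(nd$defect_present)
  expect_equal(nd$severity, "no_defect")
})

test_that("the pseudoexon assay normalizes to 91.0% and classifies mild", {
  fx <- build_cohort_fixture()
  g <- interpret_assay(fx$assay_bands[fx$assay_bands$gene == "GRM6", ], 492)
  expect_true(g$defect_present)  # novel 567-nt fragment
  expect_equal(g$pct_wt_raw, 42.0)
  expect_equal(g$pct_wt_normalized, 91.0)
  expect_equal(g$severity, "mild")
  # the flagged heteroduplex lane is excluded from quantification
  expect_false(610 %in% g$mut_lanes$fragment_length_nt)
})

test_that("fixture lane lengths equal the predicted event arithmetic", {
  fx <- build_cohort_fixture()
  meta <- fx$assay_meta[!is.na(fx$assay_meta$event_kind), ]
  for (i in seq_len(nrow(meta))) {
    pred <- predict_fragment_length(
      meta$wt_fragment_length[i],
      splice_event(meta$event_kind[i], meta$event_size[i]))
    mut <- fx$assay_bands[fx$assay_bands$hgvs_c == meta$hgvs_c[i] &
                            fx$assay_bands$gene == meta$gene[i] &
                            fx$assay_bands$construct == "mut" &
                            !fx$assay_bands$ignore, ]
    expect_true(pred %in% mut$fragment_length_nt,
                label = paste(meta$gene[i], meta$hgvs_c[i]))
  }
})

test_that("the NCSS elongation assay quantifies 78.9/21.1 and is severe", {
  fx <- build_cohort_fixture()
  u <- interpret_assay(
    fx$assay_bands[fx$assay_bands$hgvs_c == "c.4758+3A>G", ], 225)
  expect_equal(sort(u$mut_lanes$percent), c(21.1, 78.9))
  expect_equal(u$severity, "severe")
})
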
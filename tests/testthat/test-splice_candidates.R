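# SpliceAI / Alamut candidate selection.

test_that("SpliceAI rule takes the maximum delta against the threshold", {
  expect_true(spliceai_candidate(c(0, 0, 0.12, 0)))  # donor gain
  expect_false(spliceai_candidate(c(0, 0, 0, 0)))
  expect_true(spliceai_candidate(c(0.02, 0, 0, 0)))  # inclusive boundary
  expect_error(spliceai_candidate(c(NA, NA, NA, NA)), "Alamut")
})

test_that("the strict toggle flips only the exact-boundary decision", {
  strict <- splice_config(spliceai_strict = TRUE)
  grid <- c(0, 0.019, 0.02, 0.021, 0.5, 1)
  for (d in grid) {
    incl <- spliceai_candidate(c(d, 0, 0, 0))
    str <- spliceai_candidate(c(d, 0, 0, 0), strict)
    expect_equal(incl, d >= 0.02)
    expect_equal(str, d > 0.02)
  }
})

test_that("Alamut rule needs gains in at least two algorithms", {
  pairs <- validate_alamut(data.frame(
    gene = "ABCA4", hgvs_c = "x",
    algorithm = c("SSFL", "HSF"), site_kind = "donor",
    wt_score = c(67.6, 70.2), mut_score = c(79.1, 82.5),
    scale_max = 100))
  expect_true(alamut_candidate(pairs))
  one <- pairs[1, ]
  expect_false(alamut_candidate(one))
  flat <- pairs
  flat$mut_score <- flat$wt_score
  expect_false(alamut_candidate(flat))
  # de novo site: absent wild-type score with positive mutant score
  denovo <- pairs
  denovo$wt_score <- 0
  expect_true(alamut_candidate(denovo))
  expect_error(alamut_candidate(pairs[0, ]), "no Alamut")
})

test_that("fixture selection reproduces the candidate enumeration", {
  fx <- build_cohort_fixture()
  cand <- cohort_splice_candidates(fx)
  # 14 distinct individuals carry a selected candidate
  expect_equal(length(unique(cand$case_id)), 14L)
  # 13 distinct variants: 3 NCSS + 10 deep-intronic
  uv <- unique(cand[c("gene", "hgvs_c")])
  expect_equal(nrow(uv), 13L)
  v <- fx$variants
  cons <- v$consequence[match(paste(uv$gene, uv$hgvs_c),
                              paste(v$gene, v$hgvs_c))]
  expect_equal(sum(cons == "ncss"), 3L)
  expect_equal(sum(cons == "deep_intronic"), 10L)
  # the three indel variants trigger on Alamut only
  ao <- unique(cand[cand$trigger == "alamut_only", c("gene", "hgvs_c")])
  expect_equal(nrow(ao), 3L)
  expect_setequal(ao$gene, c("ABCA4", "CYP4V2", "RLBP1"))
})

test_that("sub-threshold deltas with flat Alamut pairs are not selected", {
  v <- tiny_variant(hgvs = "c.100-50A>G", consequence = "deep_intronic",
                    sai_ag = 0.01, sai_al = 0, sai_dg = 0, sai_dl = 0)
  expect_equal(nrow(select_splice_candidates(v)), 0L)
})

test_that("an indel without deltas selects via Alamut with its trigger", {
  v <- tiny_variant(hgvs = "c.100-50_100-48delinsT",
                    consequence = "deep_intronic")
  al <- data.frame(gene = "GENE1", hgvs_c = "c.100-50_100-48delinsT",
                   algorithm = c("SSFL", "HSF"), site_kind = "donor",
                   wt_score = 0, mut_score = c(80, 75), scale_max = 100)
  out <- select_splice_candidates(v, validate_alamut(al))
  expect_equal(out$trigger, "alamut_only")
  expect_equal(out$predicted_event, "unknown")
})

test_that("raising the delta threshold never adds candidates", {
  fx <- build_cohort_fixture()
  lo <- cohort_splice_candidates(fx, ird_config(
    splice = splice_config(spliceai_delta_min = 0.02)))
  hi <- cohort_splice_candidates(fx, ird_config(
    splice = splice_config(spliceai_delta_min = 0.2)))
  key <- function(d) paste(d$case_id, d$gene, d$hgvs_c)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lt(nrow(hi), nrow(lo))
})

test_that("selection does not depend on variant order", {
  fx <- build_cohort_fixture()
  a <- cohort_splice_candidates(fx)
  set.seed(9)
  fx$variants <- fx$variants[sample(nrow(fx$variants)), ]
  b <- cohort_splice_candidates(fx)
  expect_equal(a, b, ignore_attr = TRUE)
})
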
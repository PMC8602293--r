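# Frequency gating, the missense score rule, effect ordering, ROH
# scanning and the two-branch prioritization protocol.

test_that("frequency gate passes rare, absent and source-missing records", {
  expect_true(frequency_pass(c(gnomad = 0.003052)))   # rare synonymous/NCSS
  expect_false(frequency_pass(c(gnomad = 0.02)))      # above the 1% gate
  expect_true(frequency_pass(numeric(0)))             # unreported anywhere
  expect_true(frequency_pass(c(gnomad = NA, dbsnp = NA)))
  # secondary-source gates bind only when present
  expect_false(frequency_pass(c(gnomad = 0.001, dbsnp = 0.06)))
  expect_true(frequency_pass(c(gnomad = 0.001, dbsnp = 0.04)))
})

test_that("lowering any frequency never flips the gate from pass to fail", {
  set.seed(42)
  srcs <- c("gnomad", "dbsnp", "inhouse_eur", "inhouse_asian")
  for (i in 1:200) {
    f <- stats::runif(4, 0, 0.08)
    names(f) <- srcs
    keep <- stats::runif(4) < 0.7
    f <- f[keep]
    before <- frequency_pass(f)
    f2 <- f * stats::runif(length(f), 0, 1)
    if (before) expect_true(frequency_pass(f2))
  }
})

test_that("missense rule needs at least two of three thresholds", {
  expect_true(missense_causative(3.0, 20, 100))
  expect_false(missense_causative(3.0, 10, 50))   # only one passes
  expect_true(missense_causative(2.7, 15, 79))    # two inclusive passes
  expect_error(missense_causative(NA, NA, NA), "uninterpretable")
})

test_that("missense rule is monotone nondecreasing in each score", {
  set.seed(7)
  for (i in 1:100) {
    s <- c(stats::runif(1, -5, 6), stats::runif(1, 1, 40),
           stats::runif(1, 0, 215))
    base <- missense_causative(s[1], s[2], s[3])
    bump <- s + stats::runif(3, 0, 5) * c(1, 1, 1)
    bump[1] <- min(bump[1], 6.4)
    if (base) expect_true(missense_causative(bump[1], bump[2], bump[3]))
  }
})

test_that("effect ranking reproduces the prioritization order", {
  expect_equal(effect_rank("nonsense"), 1L)
  expect_equal(effect_rank("synonymous"), 7L)
  shuffled <- sample(consequence_levels()[1:7])
  expect_equal(shuffled[order(effect_rank(shuffled))],
               consequence_levels()[1:7])
  expect_gt(effect_rank("deep_intronic"), effect_rank("synonymous"))
  expect_error(effect_rank("stoploss"), "accepted vocabulary")
})

test_that("ROH scan finds long homozygous runs and respects the span gate", {
  pos <- seq(1L, by = 7000L, length.out = 60)  # ~413 kb span
  r <- roh_scan(pos, rep(FALSE, 60))
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_index, 1L)
  expect_equal(r$end_index, 60L)
  # same sites compressed under 300 kb: no run
  pos2 <- seq(1L, by = 3000L, length.out = 60)
  expect_equal(nrow(roh_scan(pos2, rep(FALSE, 60))), 0L)
  expect_error(roh_scan(c(5L, 1L), c(FALSE, FALSE)), "sorted")
})

test_that("ROH scan matches the brute-force oracle on random tracks", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(60:200, 1)
    pos <- cumsum(sample(500:9000, n, replace = TRUE))
    het <- stats::runif(n) < sample(c(0.02, 0.08, 0.3), 1)
    got <- roh_scan(pos, het)
    want <- roh_oracle(pos, het)
    expect_equal(got[c("start_index", "end_index")], want,
                 ignore_attr = TRUE)
  }
})

test_that("monoallelic branch interrogates the prior gene intronically", {
  fx <- build_cohort_fixture()
  p <- prioritize_case(fx, "Pt-14")
  expect_equal(p$branch, "monoallelic")
  expect_true("GRM6" %in% p$genes_interrogated_intronically)
  cand <- p$candidates
  expect_true(any(cand$label == "c.1355-587dup" &
                    cand$evidence == "rare_intronic_prior_gene"))
})

test_that("a common nonsense variant yields no candidates", {
  co <- ird_cohort(cases = tiny_case(),
                   variants = tiny_variant(af_gnomad = 0.02),
                   panel = tiny_panel())
  p <- prioritize_case(co, "T-1")
  expect_equal(p$branch, "no_prior_candidate")
  expect_equal(nrow(p$candidates), 0L)
  expect_equal(p$excluded$reason, "frequency_gate")
})

test_that("gate composition keeps the frameshift and drops the weak missense", {
  v <- rbind(
    tiny_variant(hgvs = "c.10del", consequence = "frameshift",
                 zygosity = "hom"),
    tiny_variant(hgvs = "c.200G>A", consequence = "missense",
                 phylop = 3.0, cadd_phred = 8, grantham = 40))
  co <- ird_cohort(cases = tiny_case(), variants = v, panel = tiny_panel())
  p <- prioritize_case(co, "T-1")
  expect_equal(p$candidates$label, "c.10del")
  expect_equal(p$excluded$reason, "missense_one_threshold")
})

test_that("prioritization is invariant to input variant order", {
  fx <- build_cohort_fixture()
  p1 <- prioritize_case(fx, "Pt-24")
  fx2 <- fx
  set.seed(3)
  fx2$variants <- fx2$variants[sample(nrow(fx2$variants)), ]
  p2 <- prioritize_case(fx2, "Pt-24")
  expect_equal(p1$candidates, p2$candidates, ignore_attr = TRUE)
  expect_equal(p1$branch, p2$branch)
})

test_that("repeat expansions are screened for every case", {
  fx <- build_cohort_fixture()
  p <- prioritize_case(fx, "Pt-4")
  expect_true(any(p$candidates$type == "repeat" &
                    p$candidates$gene == "ATXN7"))
  # a normal-range genotype is not a candidate
  p25 <- prioritize_case(fx, "Pt-25")
  expect_false(any(p25$candidates$type == "repeat"))
})
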
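# Case-level resolution and cohort accounting.

test_that("a homozygous exon-deleting SV solves a recessive case", {
  fx <- build_cohort_fixture()
  r <- resolve_case(fx, "Pt-22")
  expect_equal(r$status, "solved")
  expect_equal(r$causal_gene, "RPGRIP1")
  expect_true("biallelic_lof" %in% r$rationale_tags)
})

test_that("a heterozygous whole-gene deletion solves a dominant gene", {
  fx <- build_cohort_fixture()
  r <- resolve_case(fx, "Pt-23")
  expect_equal(r$status, "solved")
  expect_equal(r$causal_gene, "PRPF31")
  expect_true("dominant_lof_sv" %in% r$rationale_tags)
})

test_that("a no-defect assay partner leaves the case unsolved", {
  fx <- build_cohort_fixture()
  for (id in c("Pt-27", "Pt-28", "Pt-52", "Pt-61", "Pt-65")) {
    r <- resolve_case(fx, id)
    expect_equal(r$status, "unsolved", label = id)
    expect_true(any(r$evidence$label == "assay_no_defect"), label = id)
  }
})

test_that("homozygous hypomorphic and repeat-expansion genotypes resolve", {
  fx <- build_cohort_fixture()
  r15 <- resolve_case(fx, "Pt-15")
  expect_equal(r15$status, "solved")
  expect_true("hom_hypomorphic" %in% r15$rationale_tags)
  r4 <- resolve_case(fx, "Pt-4")
  expect_equal(r4$status, "solved")
  expect_equal(r4$causal_gene, "ATXN7")
  expect_true("repeat_expansion" %in% r4$rationale_tags)
})

test_that("a VUS passing all three thresholds gives likely solved", {
  fx <- build_cohort_fixture()
  r <- resolve_case(fx, "Pt-12")
  expect_equal(r$status, "likely_solved")
  expect_true("vus_supported" %in% r$rationale_tags)
})

test_that("the fixture solved set is exactly the expected proband list", {
  fx <- build_cohort_fixture()
  res <- resolve_cohort(fx)
  solved <- res$table$case_id[res$table$status %in%
                                c("solved", "likely_solved")]
  expect_setequal(solved, paste0("Pt-", 1:24))
  expect_equal(sum(res$table$status == "likely_solved"), 1L)
})

test_that("alleles referencing genes off the panel raise an error", {
  v <- tiny_variant(gene = "NOTAGENE")
  co <- ird_cohort(cases = tiny_case(), variants = v,
                   panel = tiny_panel()[0, ])
  expect_error(resolve_case(co, "T-1"), "absent from")
})

test_that("adding evidence never demotes a case", {
  fx <- build_cohort_fixture()
  base <- resolve_case(fx, "Pt-27")$status
  expect_equal(base, "unsolved")
  extra <- fx$variants[fx$variants$case_id == "Pt-27" &
                         fx$variants$prior_allele, ]
  extra$hgvs_c <- "c.999G>T"
  extra$consequence <- "nonsense"
  extra$prior_allele <- FALSE
  fx$variants <- rbind(fx$variants, extra)
  expect_equal(resolve_case(fx, "Pt-27")$status, "solved")
  # adding non-qualifying evidence to a solved case changes nothing
  fx2 <- build_cohort_fixture()
  junk <- fx2$variants[fx2$variants$case_id == "Pt-22", ][1, ]
  junk$hgvs_c <- "c.5C>T"
  junk$consequence <- "synonymous"
  junk$prior_allele <- FALSE
  junk$classification <- NA
  fx2$variants <- rbind(fx2$variants, junk)
  expect_equal(resolve_case(fx2, "Pt-22")$status, "solved")
})

test_that("cohort summary counts are exact and order-invariant", {
  fx <- build_cohort_fixture()
  res <- resolve_cohort(fx)
  s <- summarize_cohort(res, fx$cases)
  expect_equal(s$n_cases, 100L)
  expect_equal(s$n_solved, 24L)
  expect_equal(s$solved_pct, 24.0)
  expect_equal(sum(s$phenotype_counts), 100L)
  perm <- res
  set.seed(2)
  perm$table <- perm$table[sample(nrow(perm$table)), ]
  s2 <- summarize_cohort(perm, fx$cases)
  expect_equal(s2$n_solved, s$n_solved)
  expect_equal(s2$solved_ids, s$solved_ids)
  dup <- rbind(res$table, res$table[1, ])
  expect_error(summarize_cohort(dup, fx$cases), "duplicate")
})

test_that("an all-unsolved cohort summarizes to 0.0 percent", {
  co <- ird_cohort(cases = tiny_case(), variants = NULL,
                   panel = tiny_panel())
  res <- resolve_cohort(co)
  s <- summarize_cohort(res, co$cases)
  expect_equal(s$n_solved, 0L)
  expect_equal(s$solved_pct, 0.0)
})
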
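#' Population-frequency gate
#'
#' A variant passes the gate when every *present* source frequency is at
#' or below its configured maximum; sources that were not annotated never
#' fail the gate (a variant unreported in gnomAD is treated as rare, as
#' for novel indels). The binding WGS-stage rule is the gnomAD 1% gate;
#' the dbSNP and in-house gates apply only when those sources are carried
#' on the record (they describe the prior TCS/WES screening stage and are
#' supported via the same config).
#'
#' @param freqs named numeric vector with any of `gnomad`, `dbsnp`,
#'   `inhouse_eur`, `inhouse_asian`; `NA` or absent entries are skipped.
#' @param consequence effect class of the variant (deep-intronic variants
#'   are additionally screened against `intronic_max` during gene-of-
#'   interest interrogation).
#' @param cfg a [triage_config()].
#' @return `TRUE` if the variant may remain causative.
#' @export
#' @examples
#' frequency_pass(c(gnomad = 0.003052))        # rare: passes
#' frequency_pass(c(gnomad = 0.02))            # >1%: fails
#' frequency_pass(numeric(0))                  # unreported: passes
frequency_pass <- function(freqs, consequence = "other",
                           cfg = triage_config()) {
  lim <- c(gnomad = cfg$gnomad_max, dbsnp = cfg$dbsnp_max,
           inhouse_eur = cfg$inhouse_eur_max,
           inhouse_asian = cfg$inhouse_asian_max)
  if (identical(consequence, "deep_intronic"))
    lim["gnomad"] <- min(lim[["gnomad"]], cfg$intronic_max)
  for (src in names(freqs)) {
    v <- freqs[[src]]
    if (is.na(v) || !src %in% names(lim)) next
    if (v > lim[[src]]) return(FALSE)
  }
  TRUE
}

# vectorized gate over a variant table
variants_frequency_pass <- function(v, cfg = triage_config()) {
  if (nrow(v) == 0) return(logical(0))
  vapply(seq_len(nrow(v)), function(i) {
    frequency_pass(c(gnomad = v$af_gnomad[i], dbsnp = v$af_dbsnp[i],
                     inhouse_eur = v$af_inhouse_eur[i],
                     inhouse_asian = v$af_inhouse_asian[i]),
                   consequence = v$consequence[i], cfg = cfg)
  }, logical(1))
}

#' Missense causativity by in-silico score thresholds
#'
#' Counts the present scores meeting their predicted-pathogenic
#' thresholds (PhyloP >= 2.7, CADD-PHRED >= 15, Grantham >= 80,
#' inclusive) and keeps the variant causative only when at least
#' `min_passed_scores` (default two) pass — a missense variant passing
#' only one threshold is not considered causative.
#'
#' @param phylop,cadd,grantham scores; `NA` for absent.
#' @param cfg a [triage_config()].
#' @return `TRUE` if the variant remains causative. Errors when all three
#'   scores are absent (uninterpretable).
#' @export
#' @examples
#' missense_causative(3.0, 20, 100)  # all three pass -> TRUE
#' missense_causative(3.0, 10, 50)   # only one passes -> FALSE
missense_causative <- function(phylop = NA, cadd = NA, grantham = NA,
                               cfg = triage_config()) {
  present <- c(phylop = !is.na(phylop), cadd = !is.na(cadd),
               grantham = !is.na(grantham))
  if (!any(present))
    stop_field("all in-silico scores absent: missense is uninterpretable")
  passed <- sum(c(isTRUE(phylop >= cfg$phylop_min),
                  isTRUE(cadd >= cfg$cadd_min),
                  isTRUE(grantham >= cfg$grantham_min)))
  passed >= cfg$min_passed_scores
}

# number of thresholds passed (0..3); used by resolution for the
# unanimous-threshold VUS rule
missense_score_count <- function(phylop = NA, cadd = NA, grantham = NA,
                                 cfg = triage_config()) {
  sum(c(isTRUE(phylop >= cfg$phylop_min),
        isTRUE(cadd >= cfg$cadd_min),
        isTRUE(grantham >= cfg$grantham_min)))
}

#' Effect-class prioritization rank
#'
#' Total order over consequence classes used for manual prioritization:
#' nonsense (1) < frameshift (2) < canonical splice (3) < NCSS (4) <
#' in-frame indel (5) < missense (6) < synonymous (7); deep-intronic,
#' UTR and other variants rank after synonymous.
#'
#' @param consequence one or more consequence terms.
#' @return Integer rank(s); lower is prioritized earlier.
#' @export
#' @examples
#' effect_rank("nonsense")   # 1
#' effect_rank("synonymous") # 7
effect_rank <- function(consequence) {
  lv <- consequence_levels()
  idx <- match(consequence, lv)
  if (anyNA(idx))
    stop_field("unknown consequence: ",
               paste(unique(consequence[is.na(idx)]), collapse = ", "),
               "; accepted vocabulary: ", paste(lv, collapse = ", "))
  as.integer(idx)
}

#' Run-of-homozygosity scan
#'
#' Plink-style windowed scan over an ordered biallelic genotype track of
#' one chromosome. A reported run is a maximal stretch with at least
#' `roh_min_snps` sites, spanning at least `roh_min_kb` kilobases, in
#' which every sliding window of `roh_min_snps` consecutive sites
#' contains at most `roh_window_het` heterozygous calls. ROH output is
#' advisory (it flags genes for homozygous-candidate boosting) and never
#' changes any gate.
#'
#' @param pos integer vector of site positions (sorted ascending).
#' @param het logical vector, `TRUE` for heterozygous calls.
#' @param cfg a [triage_config()].
#' @return data.frame with one row per run: first/last site index,
#'   start/end position, number of sites, span in kb and het count.
#' @export
roh_scan <- function(pos, het, cfg = triage_config()) {
  stopifnot(length(pos) == length(het))
  if (is.unsorted(pos)) stop_field("genotype track must be sorted by position")
  n <- length(pos)
  w <- cfg$roh_min_snps
  out <- data.frame(start_index = integer(), end_index = integer(),
                    start_pos = integer(), end_pos = integer(),
                    n_snps = integer(), span_kb = numeric(),
                    n_het = integer())
  if (n < w) return(out)
  hetn <- as.integer(het)
  cs <- c(0L, cumsum(hetn))
  # window k covers sites k .. k+w-1
  nwin <- n - w + 1L
  win_ok <- (cs[(w + 1L):(n + 1L)] - cs[1:nwin]) <= cfg$roh_window_het
  # maximal stretches of consecutive TRUE windows -> runs [a, b + w - 1]
  r <- rle(win_ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i1 <- starts[j]; i2 <- ends[j] + w - 1L
    span_kb <- (pos[i2] - pos[i1]) / 1000
    if (span_kb < cfg$roh_min_kb) next
    out <- rbind(out, data.frame(
      start_index = i1, end_index = i2,
      start_pos = pos[i1], end_pos = pos[i2],
      n_snps = i2 - i1 + 1L, span_kb = span_kb,
      n_het = sum(hetn[i1:i2])))
  }
  rownames(out) <- NULL
  out
}

#' Two-branch case prioritization
#'
#' Applies the manual prioritization protocol for one proband. When a
#' first candidate allele was identified in prior TCS/WES testing
#' (`prior_allele` set on a variant record), the *monoallelic* branch is
#' taken: structural variants hitting the prior gene are evaluated first,
#' then rare intronic variants (frequency below `intronic_max`) of that
#' gene, then the search falls back to the genome-wide branch. With no
#' prior candidate, SV/CNV candidates are ranked first, followed by
#' small variants ordered by [effect_rank()]. Missense variants failing
#' [missense_causative()] are excluded from candidacy (but retained in
#' the evidence chain of reports); variants in genes outside the panel
#' are never candidates. Repeat expansions are screened for every case.
#' Equal-rank candidates are ordered by (gene, chrom, pos), which makes
#' the result independent of input variant order.
#'
#' @param cohort an [ird_cohort()].
#' @param case_id the proband to prioritize.
#' @param cfg a [triage_config()].
#' @return A list of class `ird_prioritization`: `case_id`, `branch`
#'   (`"monoallelic"` or `"no_prior_candidate"`), `candidates` (ordered
#'   data.frame with type, gene, label, evidence tag),
#'   `genes_interrogated_intronically`, and `excluded` (evidence-chain
#'   rows that failed a gate, with the failed gate named).
#' @export
prioritize_case <- function(cohort, case_id, cfg = triage_config()) {
  stopifnot(inherits(cohort, "ird_cohort"))
  v <- cohort$variants[cohort$variants$case_id == case_id, , drop = FALSE]
  svs <- cohort$svs[cohort$svs$case_id == case_id, , drop = FALSE]
  reps <- cohort$repeats[cohort$repeats$case_id == case_id, , drop = FALSE]
  panel <- cohort$panel

  in_panel <- v$gene %in% panel$gene
  v <- v[in_panel, , drop = FALSE]
  fp <- variants_frequency_pass(v, cfg)
  keep_missense <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(v))) {
    if (v$consequence[i] == "missense" &&
        any(!is.na(c(v$phylop[i], v$cadd_phred[i], v$grantham[i])))) {
      keep_missense[i] <- missense_causative(v$phylop[i], v$cadd_phred[i],
                                             v$grantham[i], cfg)
    }
  }
  excluded <- data.frame(
    gene = character(), hgvs_c = character(), reason = character())
  add_excl <- function(rows, reason) {
    if (nrow(rows) == 0) return()
    excluded <<- rbind(excluded, data.frame(gene = rows$gene,
                                            hgvs_c = rows$hgvs_c,
                                            reason = reason))
  }
  add_excl(v[!fp, , drop = FALSE], "frequency_gate")
  add_excl(v[fp & !keep_missense, , drop = FALSE], "missense_one_threshold")
  vv <- v[fp & keep_missense, , drop = FALSE]

  branch <- if (any(vv$prior_allele)) "monoallelic" else "no_prior_candidate"
  cand <- data.frame(type = character(), gene = character(),
                     label = character(), chrom = character(),
                     pos = integer(), rank = integer(),
                     evidence = character())
  add <- function(type, gene, label, chrom, pos, rank, evidence) {
    cand <<- rbind(cand, data.frame(type = type, gene = gene, label = label,
                                    chrom = chrom, pos = as.integer(pos),
                                    rank = as.integer(rank),
                                    evidence = evidence))
  }
  sv_rows <- function(rows, evidence) {
    for (i in seq_len(nrow(rows))) {
      hits <- genes_disrupted(rows[i, ], panel)
      hits <- hits[hits$consequence %in%
                     c("whole_gene", "multi_exon", "single_exon"), ,
                   drop = FALSE]
      for (j in seq_len(nrow(hits)))
        add("sv", hits$gene[j],
            paste0(rows$svtype[i], ":", rows$chrom[i], ":",
                   rows$start[i], "-", rows$end[i]),
            rows$chrom[i], rows$start[i], 0L, evidence)
    }
  }
  snv_rows <- function(rows, evidence) {
    for (i in seq_len(nrow(rows)))
      add("snv", rows$gene[i], rows$hgvs_c[i], rows$chrom[i], rows$pos[i],
          effect_rank(rows$consequence[i]), evidence)
  }

  genes_intronic <- character(0)
  intronic_of <- function(gene) {
    rows <- vv[vv$gene == gene & vv$consequence == "deep_intronic", ,
               drop = FALSE]
    ok <- vapply(seq_len(nrow(rows)), function(i) {
      af <- rows$af_gnomad[i]
      is.na(af) || af <= cfg$intronic_max
    }, logical(1))
    rows[ok, , drop = FALSE]
  }

  if (branch == "monoallelic") {
    prior <- vv[vv$prior_allele, , drop = FALSE]
    prior_genes <- sort(unique(prior$gene))
    snv_rows(prior, "prior_allele")
    for (g in prior_genes) {
      sv_rows(svs[vapply(seq_len(nrow(svs)), function(i) {
        h <- genes_disrupted(svs[i, ], panel); g %in% h$gene
      }, logical(1)), , drop = FALSE], "sv_prior_gene")
      di <- intronic_of(g)
      snv_rows(di, "rare_intronic_prior_gene")
      genes_intronic <- union(genes_intronic, g)
    }
    rest <- vv[!vv$prior_allele &
                 !(vv$gene %in% prior_genes &
                     vv$consequence == "deep_intronic"), , drop = FALSE]
    sv_rows(svs, "sv_genome_wide")
    snv_rows(rest[rest$consequence != "deep_intronic", , drop = FALSE],
             "effect_ranked")
  } else {
    sv_rows(svs, "sv_genome_wide")
    coding <- vv[vv$consequence != "deep_intronic", , drop = FALSE]
    snv_rows(coding, "effect_ranked")
    # once a candidate is held, interrogate rare intronic variants of its gene
    if (nrow(cand)) {
      ord <- order(cand$rank, cand$gene, cand$chrom, cand$pos)
      top_gene <- cand$gene[ord][1]
      genes_intronic <- union(genes_intronic, top_gene)
      snv_rows(intronic_of(top_gene), "rare_intronic_candidate_gene")
    }
  }

  # repeat expansions are screened for every case
  for (i in seq_len(nrow(reps))) {
    rc <- classify_repeat(reps$locus[i],
                          c(reps$allele1[i], reps$allele2[i]),
                          cohort$repeat_ranges)
    if (any(rc$class == "pathogenic_expansion"))
      add("repeat", reps$locus[i],
          paste0(reps$locus[i], "[",
                 paste(c(reps$allele1[i], reps$allele2[i]), collapse = "/"),
                 "]"),
          NA_character_, NA_integer_, 0L, "str_screen")
  }

  cand <- cand[!duplicated(cand[c("type", "gene", "label")]), , drop = FALSE]
  ev_order <- c(prior_allele = 1L, sv_prior_gene = 2L,
                rare_intronic_prior_gene = 3L, sv_genome_wide = 4L,
                effect_ranked = 5L, rare_intronic_candidate_gene = 6L,
                str_screen = 7L)
  cand <- cand[order(ev_order[cand$evidence], cand$rank, cand$gene,
                     cand$chrom, cand$pos), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(case_id = case_id, branch = branch, candidates = cand,
                 genes_interrogated_intronically = sort(genes_intronic),
                 excluded = excluded),
            class = "ird_prioritization")
}

#' @export
print.ird_prioritization <- function(x, ...) {
  cat("Prioritization for", x$case_id, "- branch:", x$branch, "\n")
  cat(nrow(x$candidates), "candidate allele(s);",
      nrow(x$excluded), "excluded by gates\n")
  if (nrow(x$candidates)) print(x$candidates, ...)
  invisible(x)
}
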
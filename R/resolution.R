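# Case-level decision logic. An allele "qualifies" (full weight) when it
# is a frequency-passed loss-of-function coding variant, a variant
# classified pathogenic/likely pathogenic, a recognized hypomorphic
# allele, a noncoding variant with an in vitro splice defect, an
# unclassified missense passing all three in-silico thresholds, a
# gene-disrupting SV, or a pathogenic repeat expansion. A VUS passing
# all three thresholds carries partial weight and can only yield
# "likely solved" next to a fully qualifying partner allele.

# Build the per-allele evidence table for one case. Assay interpretations
# and SV interpretations are computed here from the cohort tables.
allele_evidence <- function(cohort, case_id, cfg = ird_config()) {
  tcfg <- cfg$triage; acfg <- cfg$assay
  panel <- cohort$panel
  v <- cohort$variants[cohort$variants$case_id == case_id, , drop = FALSE]
  svs <- cohort$svs[cohort$svs$case_id == case_id, , drop = FALSE]
  reps <- cohort$repeats[cohort$repeats$case_id == case_id, , drop = FALSE]

  bad <- setdiff(unique(c(v$gene, reps$locus)), panel$gene)
  if (length(bad))
    stop_field("case ", case_id, ": allele references gene(s) absent from ",
               "the panel: ", paste(bad, collapse = ", "))

  ev <- data.frame(gene = character(), allele = character(),
                   type = character(), weight = integer(),
                   qual = character(), label = character(),
                   lof = logical(), severity = character())
  add <- function(gene, allele, type, weight, qual, label, lof,
                  severity = NA_character_) {
    ev <<- rbind(ev, data.frame(gene = gene, allele = allele, type = type,
                                weight = as.integer(weight), qual = qual,
                                label = label, lof = lof,
                                severity = severity))
  }

  assay_for <- function(gene, hgvs) {
    b <- cohort$assay_bands[cohort$assay_bands$gene == gene &
                              cohort$assay_bands$hgvs_c == hgvs, ,
                            drop = FALSE]
    m <- cohort$assay_meta[cohort$assay_meta$gene == gene &
                             cohort$assay_meta$hgvs_c == hgvs, ,
                           drop = FALSE]
    if (nrow(b) == 0 || nrow(m) == 0) return(NULL)
    interpret_assay(b, m$wt_fragment_length[1], acfg)
  }

  for (i in seq_len(nrow(v))) {
    w <- if (v$zygosity[i] == "hom") 2L else 1L
    cons <- v$consequence[i]
    cls <- v$classification[i]
    freq_ok <- frequency_pass(
      c(gnomad = v$af_gnomad[i], dbsnp = v$af_dbsnp[i],
        inhouse_eur = v$af_inhouse_eur[i],
        inhouse_asian = v$af_inhouse_asian[i]),
      consequence = cons, cfg = tcfg)
    type <- if (cons %in% c("ncss")) "ncss"
      else if (cons == "deep_intronic") "deep_intronic" else "coding_snv"

    # hypomorphic alleles qualify despite frequency or score softness
    if (v$hypomorphic[i]) {
      add(v$gene[i], v$hgvs_c[i], type, w, "full", "hypomorphic", FALSE)
      next
    }
    if (!freq_ok) {
      add(v$gene[i], v$hgvs_c[i], type, w, "none", "common", FALSE)
      next
    }
    if (cons %in% c("nonsense", "frameshift", "canonical_splice")) {
      add(v$gene[i], v$hgvs_c[i], type, w, "full",
          if (!is.na(cls)) cls else "lof", TRUE)
      next
    }
    if (!is.na(cls) && cls %in% c("pathogenic", "likely_pathogenic")) {
      add(v$gene[i], v$hgvs_c[i], type, w, "full", cls, FALSE)
      next
    }
    if (cons %in% c("ncss", "deep_intronic")) {
      a <- assay_for(v$gene[i], v$hgvs_c[i])
      if (!is.null(a)) {
        if (a$defect_present) {
          add(v$gene[i], v$hgvs_c[i], type, w, "full",
              paste0("assay_", a$severity), a$severity == "severe",
              a$severity)
        } else {
          add(v$gene[i], v$hgvs_c[i], type, w, "none", "assay_no_defect",
              FALSE, "no_defect")
        }
        next
      }
      add(v$gene[i], v$hgvs_c[i], type, w, "none", "untested_noncoding",
          FALSE)
      next
    }
    if (cons == "missense") {
      nscores <- missense_score_count(v$phylop[i], v$cadd_phred[i],
                                      v$grantham[i], tcfg)
      if (!is.na(cls) && cls == "vus" && nscores == 3L) {
        add(v$gene[i], v$hgvs_c[i], type, w, "vus_supported",
            "vus_all_thresholds", FALSE)
        next
      }
      if (is.na(cls) && nscores == 3L) {
        add(v$gene[i], v$hgvs_c[i], type, w, "full", "in_silico_supported",
            FALSE)
        next
      }
      add(v$gene[i], v$hgvs_c[i], type, w, "none", "insufficient_scores",
          FALSE)
      next
    }
    add(v$gene[i], v$hgvs_c[i], type, w, "none", "low_priority_class", FALSE)
  }

  for (i in seq_len(nrow(svs))) {
    itp <- interpret_sv(svs[i, ], panel)
    hits <- itp$genes_hit
    w <- if (svs$zygosity[i] == "hom") 2L else 1L
    lab <- paste0(svs$svtype[i], ":", svs$chrom[i], ":", svs$start[i], "-",
                  svs$end[i])
    for (j in seq_len(nrow(hits))) {
      disrupt <- hits$consequence[j] %in%
        c("whole_gene", "multi_exon", "single_exon")
      lof <- hits$consequence[j] == "whole_gene" ||
        itp$frame_effect == "frameshift"
      add(hits$gene[j], lab, "sv", w,
          if (disrupt) "full" else "none",
          paste0("sv_", hits$consequence[j]), disrupt && lof)
    }
  }

  for (i in seq_len(nrow(reps))) {
    rc <- classify_repeat(reps$locus[i],
                          c(reps$allele1[i], reps$allele2[i]),
                          cohort$repeat_ranges)
    n_path <- sum(rc$class == "pathogenic_expansion")
    if (n_path > 0)
      add(reps$locus[i],
          paste0(reps$locus[i], "[",
                 paste(rc$count[rc$class == "pathogenic_expansion"],
                       collapse = "/"), "]"),
          "repeat", n_path, "full", "repeat_expansion", TRUE)
  }
  ev
}

#' Resolve a single case
#'
#' Combines all per-allele evidence of one proband into a diagnostic
#' status. An autosomal recessive panel gene solves the case when it
#' carries two qualifying alleles (a homozygous allele counts twice);
#' an AD or AD-incomplete-penetrance gene solves it with a single
#' loss-of-function structural variant or a pathogenic repeat expansion.
#' The case is likely solved when one allele is a VUS passing all three
#' in-silico thresholds and the partner allele fully qualifies.
#' Everything else — including candidates whose splice assay showed no
#' defect — leaves the case unsolved.
#'
#' @param cohort an [ird_cohort()].
#' @param case_id proband identifier.
#' @param cfg an [ird_config()].
#' @return list of class `case_resolution`: `case_id`, `status`
#'   (`solved` / `likely_solved` / `unsolved`), `causal_gene`,
#'   `causal_alleles` (data.frame of allele, type, label, weight),
#'   `rationale_tags`, `evidence` (the full evidence chain).
#' @export
resolve_case <- function(cohort, case_id, cfg = ird_config()) {
  stopifnot(inherits(cohort, "ird_cohort"))
  ev <- allele_evidence(cohort, case_id, cfg)
  panel <- cohort$panel

  best <- list(status = "unsolved", gene = NA_character_,
               alleles = ev[0, ], tags = character(0), score = c(0, 0))
  for (g in unique(ev$gene)) {
    ge <- ev[ev$gene == g, , drop = FALSE]
    inh <- panel$inheritance[match(g, panel$gene)]
    full <- ge[ge$qual == "full", , drop = FALSE]
    vus <- ge[ge$qual == "vus_supported", , drop = FALSE]
    full_w <- sum(full$weight)
    status <- "unsolved"; tags <- character(0)
    if (inh %in% c("AD", "AD_incomplete_penetrance")) {
      if (any(full$type == "sv" & full$lof)) {
        status <- "solved"; tags <- c(tags, "dominant_lof_sv")
      }
      if (any(full$type == "repeat")) {
        status <- "solved"; tags <- c(tags, "repeat_expansion")
      }
    } else { # AR (and XL treated recessively)
      if (full_w >= 2) {
        status <- "solved"
        if (any(full$type == "repeat")) tags <- c(tags, "repeat_expansion")
        if (all(full$lof)) tags <- c(tags, "biallelic_lof")
        if (any(full$label == "hypomorphic" & full$weight == 2))
          tags <- c(tags, "hom_hypomorphic")
        if (any(!is.na(full$severity) & full$severity == "severe"))
          tags <- c(tags, "assay_severe")
      } else if (full_w == 1 && nrow(vus) >= 1) {
        status <- "likely_solved"
        tags <- c(tags, "vus_supported")
      }
    }
    if (status == "unsolved") next
    rank <- c(ifelse(status == "solved", 2, 1), full_w)
    better <- rank[1] > best$score[1] ||
      (rank[1] == best$score[1] && rank[2] > best$score[2]) ||
      (all(rank == best$score) && (is.na(best$gene) || g < best$gene))
    if (better) {
      causal <- rbind(full, vus)
      best <- list(status = status, gene = g, alleles = causal,
                   tags = unique(tags), score = rank)
    }
  }
  structure(list(case_id = case_id, status = best$status,
                 causal_gene = best$gene,
                 causal_alleles = best$alleles[
                   c("allele", "type", "label", "weight", "severity")],
                 rationale_tags = best$tags, evidence = ev),
            class = "case_resolution")
}

#' Resolve every case of a cohort
#'
#' @param cohort an [ird_cohort()].
#' @param cfg an [ird_config()].
#' @return object of class `ird_resolution`: a list with `table` (one row
#'   per case: case_id, status, causal_gene, rationale) and `details`
#'   (the per-case `case_resolution` objects).
#' @export
resolve_cohort <- function(cohort, cfg = ird_config()) {
  stopifnot(inherits(cohort, "ird_cohort"))
  det <- lapply(cohort$cases$case_id, function(id)
    resolve_case(cohort, id, cfg))
  names(det) <- cohort$cases$case_id
  tab <- data.frame(
    case_id = cohort$cases$case_id,
    status = vapply(det, function(d) d$status, character(1)),
    causal_gene = vapply(det, function(d) d$causal_gene, character(1)),
    rationale = vapply(det, function(d)
      paste(d$rationale_tags, collapse = ";"), character(1)),
    row.names = NULL)
  structure(list(table = tab, details = det), class = "ird_resolution")
}

#' @export
print.ird_resolution <- function(x, ...) {
  n <- nrow(x$table)
  ns <- sum(x$table$status %in% c("solved", "likely_solved"))
  cat(sprintf("Cohort resolution: %d/%d cases solved or likely solved (%.1f%%)\n",
              ns, n, 100 * ns / n))
  print(table(x$table$status))
  invisible(x)
}

#' Cohort diagnostic-yield summary
#'
#' Exact counts of solved (including likely solved) cases, the solved
#' percentage at one decimal, per-phenotype counts, and counts of causal
#' allele types (coding SNV, NCSS, deep-intronic, SV, repeat) across
#' solved cases. Totals are invariant to case order.
#'
#' @param resolution an `ird_resolution` (or its `table`).
#' @param cases the cohort case table.
#' @return list of class `ird_cohort_summary`.
#' @export
summarize_cohort <- function(resolution, cases) {
  tab <- if (inherits(resolution, "ird_resolution")) resolution$table
    else resolution
  if (anyDuplicated(tab$case_id))
    stop_field("duplicate case_id in resolution table")
  if (anyDuplicated(cases$case_id))
    stop_field("duplicate case_id in case table")
  n <- nrow(cases)
  solved_ids <- tab$case_id[tab$status %in% c("solved", "likely_solved")]
  ns <- length(solved_ids)
  phen <- table(factor(cases$phenotype, levels = phenotype_levels()))
  vt <- c(coding_snv = 0L, ncss = 0L, deep_intronic = 0L, sv = 0L,
          repeat_expansion = 0L)
  if (inherits(resolution, "ird_resolution")) {
    for (id in solved_ids) {
      al <- resolution$details[[id]]$causal_alleles
      for (ty in al$type) {
        key <- switch(ty, coding_snv = "coding_snv", ncss = "ncss",
                      deep_intronic = "deep_intronic", sv = "sv",
                      "repeat" = "repeat_expansion")
        vt[key] <- vt[key] + 1L
      }
    }
  }
  structure(list(n_cases = n, n_solved = ns,
                 solved_pct = round(100 * ns / n, 1),
                 solved_ids = sort(solved_ids),
                 phenotype_counts = phen,
                 variant_type_counts = vt),
            class = "ird_cohort_summary")
}

#' @export
print.ird_cohort_summary <- function(x, ...) {
  cat(sprintf("%d cases, %d solved or likely solved (%.1f%%)\n",
              x$n_cases, x$n_solved, x$solved_pct))
  cat("Causal allele types among solved cases:\n")
  print(x$variant_type_counts)
  invisible(x)
}
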
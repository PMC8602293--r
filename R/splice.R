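#' SpliceAI candidacy
#'
#' A variant is a splice-assay candidate when at least one of its four
#' delta scores (acceptor gain/loss, donor gain/loss) reaches the
#' threshold (default 0.02, inclusive; a strict `>` toggle is available
#' because the boundary behaviour is unobservable from worked examples).
#'
#' @param deltas numeric vector of up to four delta scores in \[0, 1\]
#'   (named or unnamed). Must be present: indels for which SpliceAI
#'   provides no scores take the Alamut-only path instead.
#' @param cfg a [splice_config()].
#' @return `TRUE`/`FALSE`. Errors when the delta block is absent.
#' @export
#' @examples
#' spliceai_candidate(c(ag = 0, al = 0, dg = 0.12, dl = 0)) # TRUE
spliceai_candidate <- function(deltas, cfg = splice_config()) {
  if (is.null(deltas) || length(deltas) == 0 || all(is.na(deltas)))
    stop_field("SpliceAI delta block absent: use the Alamut-only path ",
               "(alamut_candidate) for this variant")
  m <- max(deltas, na.rm = TRUE)
  if (cfg$spliceai_strict) m > cfg$spliceai_delta_min
  else m >= cfg$spliceai_delta_min
}

#' Alamut-style candidacy from algorithm score pairs
#'
#' A variant is a candidate when at least `alamut_min_algorithms`
#' (default two) of the evaluated algorithms show a gained or
#' strengthened splice site: the mutant score exceeds the wild-type score
#' by at least `alamut_min_rel_increase` of the algorithm's scale maximum,
#' or a site appears de novo (wild-type score absent or zero with a
#' positive mutant score).
#'
#' @param pairs data.frame of score pairs ([validate_alamut()] columns
#'   algorithm, site_kind, wt_score, mut_score, scale_max).
#' @param cfg a [splice_config()].
#' @return `TRUE`/`FALSE`. Errors on an empty pair list.
#' @export
alamut_candidate <- function(pairs, cfg = splice_config()) {
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_field("no Alamut score pairs supplied")
  gained <- vapply(seq_len(nrow(pairs)), function(i) {
    wt <- pairs$wt_score[i]; mut <- pairs$mut_score[i]
    if (is.na(mut)) return(FALSE)
    if (is.na(wt) || wt == 0) return(mut > 0)
    (mut - wt) >= cfg$alamut_min_rel_increase * pairs$scale_max[i]
  }, logical(1))
  # count algorithms (not pairs) showing a gain
  length(unique(pairs$algorithm[gained])) >= cfg$alamut_min_algorithms
}

#' Select splice-assay candidates among a case's rare variants
#'
#' Applies the OR-combined selection rule to noncanonical splice-site and
#' deep-intronic variants that already passed frequency gating: a variant
#' is selected when its SpliceAI delta block triggers
#' [spliceai_candidate()], or — when the delta block is absent, as for
#' indels SpliceAI cannot score — when its Alamut score pairs trigger
#' [alamut_candidate()]. The predicted event is taken from the
#' `predicted_event` annotation on the record when supplied, else
#' `"unknown"`. Selection is independent of input order.
#'
#' @param variants variant table rows to consider (typically the NCSS and
#'   deep-intronic variants of a gene of interest, already
#'   frequency-passed).
#' @param alamut Alamut score-pair table (matched by gene + hgvs_c).
#' @param cfg a [splice_config()].
#' @return data.frame with one row per selected candidate: case_id, gene,
#'   hgvs_c, trigger (`"spliceai"` or `"alamut_only"`), predicted_event.
#' @export
select_splice_candidates <- function(variants, alamut = NULL,
                                     cfg = splice_config()) {
  variants <- normalize_variants(variants)
  keep <- variants$consequence %in% c("ncss", "deep_intronic")
  v <- variants[keep, , drop = FALSE]
  out <- data.frame(case_id = character(), gene = character(),
                    hgvs_c = character(), trigger = character(),
                    predicted_event = character())
  for (i in seq_len(nrow(v))) {
    deltas <- c(v$sai_ag[i], v$sai_al[i], v$sai_dg[i], v$sai_dl[i])
    trigger <- NA_character_
    if (!all(is.na(deltas))) {
      if (spliceai_candidate(deltas, cfg)) trigger <- "spliceai"
    } else {
      pairs <- NULL
      if (!is.null(alamut) && nrow(alamut))
        pairs <- alamut[alamut$gene == v$gene[i] &
                          alamut$hgvs_c == v$hgvs_c[i], , drop = FALSE]
      if (!is.null(pairs) && nrow(pairs) && alamut_candidate(pairs, cfg))
        trigger <- "alamut_only"
    }
    if (!is.na(trigger)) {
      ev <- v$predicted_event[i]
      out <- rbind(out, data.frame(
        case_id = v$case_id[i], gene = v$gene[i], hgvs_c = v$hgvs_c[i],
        trigger = trigger,
        predicted_event = if (is.na(ev)) "unknown" else ev))
    }
  }
  out <- out[order(out$case_id, out$gene, out$hgvs_c), , drop = FALSE]
  rownames(out) <- NULL
  out
}
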
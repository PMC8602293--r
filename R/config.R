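#' Triage configuration
#'
#' Thresholds for frequency gating, the missense in-silico score rule and
#' run-of-homozygosity (ROH) scanning. Defaults are the working values of
#' the WGS-stage protocol: gnomAD minor allele frequency gate of 1%
#' (a variant above it is not considered causative), dbSNP 5% and the
#' in-house European (1%) / Asian (2%) gates used at the prior
#' TCS/WES screening stage (applied only when those sources are annotated
#' on a record), rare-intronic interrogation at 1%, missense predicted
#' pathogenic thresholds PhyloP >= 2.7, CADD-PHRED >= 15, Grantham >= 80
#' with at least two of the three required, and plink-style ROH parameters
#' (window-het = 3, snp = 50, kb = 300).
#'
#' @param gnomad_max,dbsnp_max,inhouse_eur_max,inhouse_asian_max per-source
#'   maximum allele frequency (fractions in (0, 1]).
#' @param intronic_max allele-frequency ceiling for rare intronic
#'   interrogation of a gene of interest.
#' @param phylop_min,cadd_min,grantham_min predicted-pathogenic score
#'   thresholds (inclusive).
#' @param min_passed_scores minimum number of present scores that must meet
#'   their threshold for a missense variant to remain causative (1..3).
#' @param roh_window_het maximum heterozygous calls per 50-site window.
#' @param roh_min_snps minimum number of sites in a reported ROH (also the
#'   sliding-window size).
#' @param roh_min_kb minimum ROH span in kilobases.
#' @return A list of class `triage_config`.
#' @export
#' @examples
#' cfg <- triage_config()
#' frequency_pass(c(gnomad = 0.003052), cfg = cfg)
triage_config <- function(gnomad_max = 0.01, dbsnp_max = 0.05,
                          inhouse_eur_max = 0.01, inhouse_asian_max = 0.02,
                          intronic_max = 0.01,
                          phylop_min = 2.7, cadd_min = 15, grantham_min = 80,
                          min_passed_scores = 2,
                          roh_window_het = 3, roh_min_snps = 50,
                          roh_min_kb = 300) {
  fr <- c(gnomad_max = gnomad_max, dbsnp_max = dbsnp_max,
          inhouse_eur_max = inhouse_eur_max,
          inhouse_asian_max = inhouse_asian_max, intronic_max = intronic_max)
  if (any(fr <= 0 | fr > 1))
    stop_field("frequency gates must be fractions in (0, 1]")
  if (!min_passed_scores %in% 1:3)
    stop_field("min_passed_scores must be 1, 2 or 3")
  structure(list(gnomad_max = gnomad_max, dbsnp_max = dbsnp_max,
                 inhouse_eur_max = inhouse_eur_max,
                 inhouse_asian_max = inhouse_asian_max,
                 intronic_max = intronic_max,
                 phylop_min = phylop_min, cadd_min = cadd_min,
                 grantham_min = grantham_min,
                 min_passed_scores = min_passed_scores,
                 roh_window_het = roh_window_het,
                 roh_min_snps = roh_min_snps, roh_min_kb = roh_min_kb),
            class = "triage_config")
}

#' Splice-candidate selection configuration
#'
#' @param spliceai_delta_min minimum SpliceAI delta score (any of acceptor
#'   gain/loss, donor gain/loss) for candidacy. Default 0.02.
#' @param spliceai_strict if `TRUE` the comparison is strictly greater
#'   than the threshold; the default is inclusive (`>=`).
#' @param spliceai_context_bp metadata only: sequence context used when the
#'   delta scores were computed upstream (scores are consumed as inputs).
#' @param alamut_min_algorithms number of Alamut-embedded algorithms that
#'   must show a gained or strengthened site (default 2).
#' @param alamut_min_rel_increase minimum score increase as a fraction of
#'   the algorithm's scale maximum (default 0.05).
#' @return A list of class `splice_config`.
#' @export
splice_config <- function(spliceai_delta_min = 0.02, spliceai_strict = FALSE,
                          spliceai_context_bp = 500L,
                          alamut_min_algorithms = 2L,
                          alamut_min_rel_increase = 0.05) {
  if (spliceai_delta_min <= 0 || spliceai_delta_min >= 1)
    stop_field("spliceai_delta_min must lie in (0, 1)")
  if (!alamut_min_algorithms %in% 1:5)
    stop_field("alamut_min_algorithms must be in 1..5")
  structure(list(spliceai_delta_min = spliceai_delta_min,
                 spliceai_strict = isTRUE(spliceai_strict),
                 spliceai_context_bp = as.integer(spliceai_context_bp),
                 alamut_min_algorithms = as.integer(alamut_min_algorithms),
                 alamut_min_rel_increase = alamut_min_rel_increase),
            class = "splice_config")
}

#' Splice-assay interpretation configuration
#'
#' @param severe_max_pct normalized wild-type percentage strictly below
#'   which an allele is severe (default 25, the protocol-defining cut).
#' @param mild_min_pct normalized wild-type percentage at or above which an
#'   allele is mild (default 75); values in between are moderate.
#' @param novel_fragment_min_pct a mutant-construct fragment absent from
#'   the wild-type construct counts as a splice defect only above this
#'   share of total lane intensity (percent, default 5).
#' @param wt_drop_min_pct loss of wild-type fragment share (mutant vs.
#'   wild-type construct, percentage points) beyond which a defect is
#'   called even without a novel fragment (default 10).
#' @param length_tol_nt fragment lengths within this many nucleotides are
#'   treated as the same band when matching lanes across constructs.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(severe_max_pct = 25, mild_min_pct = 75,
                         novel_fragment_min_pct = 5, wt_drop_min_pct = 10,
                         length_tol_nt = 0L) {
  if (severe_max_pct >= mild_min_pct)
    stop_field("severe_max_pct must be below mild_min_pct")
  structure(list(severe_max_pct = severe_max_pct,
                 mild_min_pct = mild_min_pct,
                 novel_fragment_min_pct = novel_fragment_min_pct,
                 wt_drop_min_pct = wt_drop_min_pct,
                 length_tol_nt = as.integer(length_tol_nt)),
            class = "assay_config")
}

#' Combined pipeline configuration
#'
#' Bundles the per-stage configurations consumed by [run_cohort()] and
#' [resolve_cohort()]. All thresholds are overridable; [read_config()] /
#' [write_config()] round-trip the structure through YAML with keys
#' mirroring the field names.
#'
#' @param triage a [triage_config()].
#' @param splice a [splice_config()].
#' @param assay an [assay_config()].
#' @return A list of class `ird_config`.
#' @export
ird_config <- function(triage = triage_config(), splice = splice_config(),
                       assay = assay_config()) {
  stopifnot(inherits(triage, "triage_config"),
            inherits(splice, "splice_config"),
            inherits(assay, "assay_config"))
  structure(list(triage = triage, splice = splice, assay = assay),
            class = "ird_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path file path.
#' @param cfg an [ird_config()] object (for writing).
#' @return `read_config()` returns an `ird_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ird_config(
    triage = do.call(triage_config, raw$triage %||% list()),
    splice = do.call(splice_config, raw$splice %||% list()),
    assay  = do.call(assay_config,  raw$assay  %||% list())
  )
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ird_config"))
  yaml::write_yaml(lapply(cfg, unclass), path)
  invisible(path)
}
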
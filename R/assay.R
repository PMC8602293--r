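#' Quantify RT-PCR fragments from a lane table
#'
#' Converts gel-band intensities into percentages of total product:
#' `percent_i = 100 * intensity_i / sum(intensity)`. Lanes flagged
#' `ignore` (heteroduplex or artifact bands) are excluded before
#' normalization. Output percentages sum to 100 and are invariant to
#' rescaling all intensities by a positive constant.
#'
#' @param lengths fragment lengths in nt.
#' @param intensities nonnegative intensities in arbitrary units.
#' @param ignore optional logical vector of lanes to exclude.
#' @return data.frame: fragment_length_nt, percent.
#' @export
#' @examples
#' quantify_fragments(c(332, 225), c(78.9, 21.1))
quantify_fragments <- function(lengths, intensities, ignore = NULL) {
  stopifnot(length(lengths) == length(intensities))
  if (!is.null(ignore)) {
    lengths <- lengths[!ignore]; intensities <- intensities[!ignore]
  }
  if (length(intensities) == 0 || sum(intensities) <= 0)
    stop_field("total lane intensity must be positive")
  if (any(intensities < 0)) stop_field("intensities must be >= 0")
  data.frame(fragment_length_nt = as.integer(lengths),
             percent = 100 * intensities / sum(intensities))
}

#' Hypothesized splice event
#'
#' A splice event of a given kind and size; the reading-frame consequence
#' is derived from the size (`in_frame` iff `size_nt` is a multiple of 3).
#'
#' @param kind one of `pseudoexon_insertion`, `exon_elongation`,
#'   `exon_skipping`, `partial_exon_deletion`.
#' @param size_nt positive event size in nucleotides.
#' @return list of class `splice_event` with `kind`, `size_nt`, `frame`.
#' @export
#' @examples
#' splice_event("pseudoexon_insertion", 75)$frame  # in-frame (25 aa)
splice_event <- function(kind, size_nt) {
  kinds <- c("pseudoexon_insertion", "exon_elongation", "exon_skipping",
             "partial_exon_deletion")
  if (!kind %in% kinds)
    stop_field("event kind must be one of: ", paste(kinds, collapse = ", "))
  size_nt <- as.integer(size_nt)
  if (is.na(size_nt) || size_nt <= 0) stop_field("size_nt must be positive")
  structure(list(kind = kind, size_nt = size_nt,
                 frame = if (size_nt %% 3 == 0) "in_frame" else "frameshift"),
            class = "splice_event")
}

#' Expected RT-PCR fragment length under a splice event
#'
#' Insertions (pseudoexon insertion, exon elongation) add the event size
#' to the wild-type fragment; exon skipping and partial exon deletion
#' subtract it.
#'
#' @param wt_len wild-type fragment length in nt.
#' @param event a [splice_event()].
#' @return Integer expected mutant fragment length in nt.
#' @export
#' @examples
#' predict_fragment_length(225, splice_event("exon_elongation", 107))   # 332
#' predict_fragment_length(274, splice_event("pseudoexon_insertion", 104)) # 378
#' predict_fragment_length(492, splice_event("pseudoexon_insertion", 75))  # 567
predict_fragment_length <- function(wt_len, event) {
  stopifnot(inherits(event, "splice_event"))
  wt_len <- as.integer(wt_len)
  if (event$kind %in% c("pseudoexon_insertion", "exon_elongation"))
    return(wt_len + event$size_nt)
  if (event$size_nt >= wt_len)
    stop_field("skipped/deleted size must be smaller than the wild-type ",
               "fragment")
  wt_len - event$size_nt
}

#' Normalized wild-type percentage
#'
#' Normalizes the wild-type fragment share of the mutant construct to
#' that of the wild-type construct: `100 * mut_wt_pct / wtconstruct_wt_pct`,
#' capped at 100. The ratio is rounded to the nearest integer and
#' reported at one decimal, reproducing the published convention
#' (42/46 x 100 reports as 91.0).
#'
#' @param mut_wt_pct percent wild-type fragment in the mutant construct.
#' @param wtconstruct_wt_pct percent wild-type fragment in the wild-type
#'   construct (must be positive).
#' @return Normalized percentage (one-decimal value).
#' @export
#' @examples
#' normalized_wt_percent(42, 46)  # 91.0
#' normalized_wt_percent(0, 76)   # 0.0
normalized_wt_percent <- function(mut_wt_pct, wtconstruct_wt_pct) {
  if (is.na(wtconstruct_wt_pct) || wtconstruct_wt_pct <= 0)
    stop_field("wild-type construct wild-type percentage must be positive")
  r <- 100 * mut_wt_pct / wtconstruct_wt_pct
  r <- min(r, 100)
  round(round(r), 1)
}

#' Allele severity from remaining wild-type percentage
#'
#' Below 25% remaining wild-type product the allele is `severe` (the
#' defining cut of the protocol); at or above 75% it is `mild` (the
#' label given to a 91% remaining-wild-type allele); the band in between
#' is `moderate`. Boundaries are config-overridable.
#'
#' @param pct_wt percent wild-type in \[0, 100\].
#' @param cfg an [assay_config()].
#' @return `"severe"`, `"moderate"` or `"mild"`.
#' @export
#' @examples
#' classify_allele_severity(21.1)  # severe
#' classify_allele_severity(91.0)  # mild
classify_allele_severity <- function(pct_wt, cfg = assay_config()) {
  if (is.na(pct_wt) || pct_wt < 0 || pct_wt > 100)
    stop_field("pct_wt must lie in [0, 100]")
  if (pct_wt < cfg$severe_max_pct) "severe"
  else if (pct_wt >= cfg$mild_min_pct) "mild"
  else "moderate"
}

#' Interpret a splice assay
#'
#' Quantifies wild-type and mutant construct lanes, decides whether the
#' mutant construct shows a splice defect, and classifies allele
#' severity. A defect is present when the mutant lanes contain a
#' fragment absent from the wild-type construct above an intensity
#' tolerance, or when the wild-type fragment share drops relative to the
#' wild-type construct beyond `wt_drop_min_pct` (this covers constructs
#' whose wild-type assay already shows a minor aberrant band). Without a
#' defect the interpretation is `no_defect` (downstream label: likely
#' benign). With a defect, the raw wild-type percentage is read off the
#' mutant lanes, normalized to the wild-type construct via
#' [normalized_wt_percent()] (percentages rounded to the nearest integer
#' before the ratio, the published convention), and severity classified
#' from the normalized value.
#'
#' @param bands band table for one assay (both constructs;
#'   [validate_assay_bands()]).
#' @param wt_fragment_length length in nt of the correctly spliced
#'   fragment.
#' @param cfg an [assay_config()].
#' @return list of class `assay_interpretation`: `defect_present`,
#'   `pct_wt_raw`, `pct_wt_normalized`, `severity` (`"severe"`,
#'   `"moderate"`, `"mild"` or `"no_defect"`), plus the quantified lane
#'   tables.
#' @export
interpret_assay <- function(bands, wt_fragment_length,
                            cfg = assay_config()) {
  bands <- validate_assay_bands(bands)
  wt <- bands[bands$construct == "wt" & !bands$ignore, , drop = FALSE]
  mut <- bands[bands$construct == "mut" & !bands$ignore, , drop = FALSE]
  if (nrow(wt) == 0 || nrow(mut) == 0)
    stop_field("both constructs must have at least one quantifiable lane")
  qwt <- quantify_fragments(wt$fragment_length_nt, wt$intensity)
  qmut <- quantify_fragments(mut$fragment_length_nt, mut$intensity)

  match_len <- function(len, ref)
    any(abs(ref - len) <= cfg$length_tol_nt)
  novel <- vapply(seq_len(nrow(qmut)), function(i) {
    !match_len(qmut$fragment_length_nt[i], qwt$fragment_length_nt) &&
      qmut$percent[i] > cfg$novel_fragment_min_pct
  }, logical(1))

  wt_pct_of <- function(q) {
    hit <- abs(q$fragment_length_nt - wt_fragment_length) <= cfg$length_tol_nt
    if (any(hit)) sum(q$percent[hit]) else 0
  }
  raw_mut <- wt_pct_of(qmut)
  raw_wtc <- wt_pct_of(qwt)
  wt_loss <- raw_mut < raw_wtc - cfg$wt_drop_min_pct
  defect <- any(novel) || wt_loss

  if (!defect) {
    res <- list(defect_present = FALSE, pct_wt_raw = raw_mut,
                pct_wt_normalized = NA_real_, severity = "no_defect")
  } else {
    norm <- normalized_wt_percent(round(raw_mut), max(round(raw_wtc), 1))
    res <- list(defect_present = TRUE, pct_wt_raw = raw_mut,
                pct_wt_normalized = norm,
                severity = classify_allele_severity(norm, cfg))
  }
  res$wt_lanes <- qwt
  res$mut_lanes <- qmut
  res$wt_fragment_length <- as.integer(wt_fragment_length)
  structure(res, class = "assay_interpretation")
}

#' @export
print.assay_interpretation <- function(x, ...) {
  if (!x$defect_present) {
    cat("No splice defect (mutant lanes match the wild-type construct)\n")
  } else {
    cat(sprintf(
      "Splice defect: %.1f%% wild-type fragment raw, %.1f%% normalized -> %s allele\n",
      x$pct_wt_raw, x$pct_wt_normalized, x$severity))
  }
  invisible(x)
}
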
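#' Structural-variant length
#'
#' Length in base pairs of a 1-based inclusive interval:
#' `end - start + 1`. The 26,682-bp whole-gene deletion spanning
#' g.54106454-54133135 reports as 26.68 kb at two decimals.
#'
#' @param start,end 1-based inclusive breakpoint coordinates (first and
#'   last affected base).
#' @return Integer length in bp.
#' @export
#' @examples
#' sv_length(54106454, 54133135)  # 26682
#' sv_length(100, 100)            # 1
sv_length <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end < start)) stop_field("end must be >= start")
  as.integer(end - start + 1)
}

#' Breakpoint junction microhomology
#'
#' Finds the longest stretch of identical sequence shared by the two
#' junction flanks of a structural variant: the longest `k` such that the
#' `k`-suffix of the retained left context equals the `k`-prefix of the
#' sequence at the right junction. `N` bases never match. Such
#' microhomology is evidence of the repair mechanism that produced the
#' breakpoint (e.g., microhomology-mediated end joining).
#'
#' @param left_flank sequence ending at the left breakpoint (inner-edge
#'   anchored).
#' @param right_flank sequence beginning at the right breakpoint.
#' @return list with `length` and `sequence` (`""` when none).
#' @export
#' @examples
#' microhomology("TTACGTACGTACGT", "ACGTACGTACGTGG")$length  # 12
microhomology <- function(left_flank, right_flank) {
  if (is.na(left_flank) || is.na(right_flank) ||
      !nzchar(left_flank) || !nzchar(right_flank))
    stop_field("both flank sequences must be nonempty")
  for (s in c(left_flank, right_flank))
    if (!grepl("^[ACGTN]+$", s))
      stop_field("flank sequences must be DNA over {A,C,G,T,N}")
  l <- strsplit(left_flank, "")[[1]]
  r <- strsplit(right_flank, "")[[1]]
  kmax <- min(length(l), length(r))
  best <- 0L
  for (k in seq_len(kmax)) {
    suf <- l[(length(l) - k + 1L):length(l)]
    pre <- r[1:k]
    if (all(suf == pre) && !any(suf == "N")) best <- k
  }
  list(length = best,
       sequence = if (best > 0)
         paste(r[1:best], collapse = "") else "")
}

#' Genes disrupted by a structural variant
#'
#' Classifies the consequence of an SV for every overlapped panel gene:
#' `whole_gene` when the SV covers the full gene span, `multi_exon` /
#' `single_exon` by the number of exons overlapped, `promoter_only` when
#' only the promoter interval is hit, and `intronic_only` for an
#' overlap touching neither exons nor promoter.
#'
#' @param sv one-row SV data.frame (columns chrom, start, end).
#' @param panel validated gene panel with exon list-column.
#' @return data.frame: gene, consequence, n_exons, deleted_coding_bp.
#' @export
genes_disrupted <- function(sv, panel) {
  stopifnot(nrow(sv) == 1)
  s <- sv$start[1]; e <- sv$end[1]; chrom <- sv$chrom[1]
  out <- data.frame(gene = character(), consequence = character(),
                    n_exons = integer(), deleted_coding_bp = integer())
  for (i in seq_len(nrow(panel))) {
    if (panel$chrom[i] != chrom) next
    gs <- panel$start[i]; ge <- panel$end[i]
    ps <- panel$promoter_start[i]; pe <- panel$promoter_end[i]
    gene_hit <- s <= ge && e >= gs
    prom_hit <- !is.na(ps) && s <= pe && e >= ps
    if (!gene_hit && !prom_hit) next
    if (gene_hit && s <= gs && e >= ge) {
      out <- rbind(out, data.frame(gene = panel$gene[i],
                                   consequence = "whole_gene",
                                   n_exons = nrow(panel$exons[[i]] %||%
                                                    data.frame()),
                                   deleted_coding_bp = NA_integer_))
      next
    }
    ex <- panel$exons[[i]]
    n_hit <- 0L; coding <- 0L
    if (!is.null(ex) && nrow(ex)) {
      for (j in seq_len(nrow(ex))) {
        ov <- min(e, ex$end[j]) - max(s, ex$start[j]) + 1L
        if (ov > 0) { n_hit <- n_hit + 1L; coding <- coding + ov }
      }
    }
    cons <- if (n_hit >= 2) "multi_exon"
      else if (n_hit == 1) "single_exon"
      else if (prom_hit) "promoter_only"
      else "intronic_only"
    out <- rbind(out, data.frame(gene = panel$gene[i], consequence = cons,
                                 n_exons = n_hit,
                                 deleted_coding_bp =
                                   if (n_hit > 0) coding else NA_integer_))
  }
  rownames(out) <- NULL
  out
}

#' Interpret a structural variant against the gene panel
#'
#' Combines length, per-gene disruption consequence, junction
#' microhomology (when flank sequences are supplied) and the reading-frame
#' effect. The frame effect of an exonic deletion is `frameshift` when
#' the summed deleted coding length is not a multiple of three,
#' `in_frame` when it is, `regulatory` for promoter-only hits and
#' `unknown` otherwise.
#'
#' @param sv one-row SV data.frame.
#' @param panel validated gene panel.
#' @return list of class `sv_interpretation`: `length_bp`, `genes_hit`,
#'   `microhomology_len`, `microhomology_seq`, `frame_effect`.
#' @export
interpret_sv <- function(sv, panel) {
  stopifnot(nrow(sv) == 1)
  hits <- genes_disrupted(sv, panel)
  mh_len <- NA_integer_; mh_seq <- NA_character_
  if (!is.na(sv$left_flank[1]) && !is.na(sv$right_flank[1]) &&
      nzchar(sv$left_flank[1]) && nzchar(sv$right_flank[1])) {
    mh <- microhomology(sv$left_flank[1], sv$right_flank[1])
    mh_len <- mh$length; mh_seq <- mh$sequence
  }
  frame <- "unknown"
  if (nrow(hits)) {
    if (any(hits$consequence %in% c("single_exon", "multi_exon"))) {
      coding <- sum(hits$deleted_coding_bp[
        hits$consequence %in% c("single_exon", "multi_exon")], na.rm = TRUE)
      frame <- if (coding %% 3 == 0) "in_frame" else "frameshift"
    } else if (any(hits$consequence == "whole_gene")) {
      frame <- "frameshift"  # complete loss of product
    } else if (all(hits$consequence == "promoter_only")) {
      frame <- "regulatory"
    }
  }
  structure(list(chrom = sv$chrom[1], start = sv$start[1], end = sv$end[1],
                 svtype = sv$svtype[1],
                 length_bp = sv_length(sv$start[1], sv$end[1]),
                 genes_hit = hits,
                 microhomology_len = mh_len, microhomology_seq = mh_seq,
                 frame_effect = frame),
            class = "sv_interpretation")
}

#' @export
print.sv_interpretation <- function(x, ...) {
  cat(sprintf("%s %s:%d-%d (%.2f kb), frame effect: %s\n",
              x$svtype, x$chrom, x$start, x$end, x$length_bp / 1000,
              x$frame_effect))
  if (!is.na(x$microhomology_len) && x$microhomology_len > 0)
    cat(sprintf("junction microhomology: %d bp (%s)\n",
                x$microhomology_len, x$microhomology_seq))
  if (nrow(x$genes_hit)) print(x$genes_hit, ...)
  invisible(x)
}

#' Classify a repeat genotype against locus ranges
#'
#' Partitions per-allele repeat counts into `normal` (within the
#' wild-type range), `pathogenic_expansion` (within the pathogenic
#' range) or `indeterminate` (the gap between ranges, or beyond the
#' documented pathogenic maximum).
#'
#' @param locus locus identifier (e.g. `"ATXN7"`).
#' @param counts integer vector of per-allele repeat counts.
#' @param ranges repeat-locus range table ([validate_repeat_ranges()]).
#' @return data.frame: locus, allele count, class.
#' @export
#' @examples
#' rng <- data.frame(locus = "ATXN7", normal_min = 3, normal_max = 19,
#'                   pathogenic_min = 37, pathogenic_max = 460)
#' classify_repeat("ATXN7", c(10, 70), rng)
classify_repeat <- function(locus, counts, ranges) {
  r <- ranges[ranges$locus == locus, , drop = FALSE]
  if (nrow(r) == 0)
    stop_field("unknown repeat locus: ", locus,
               " (not in the range table)")
  counts <- as.integer(counts)
  if (any(counts < 1L)) stop_field("repeat counts must be >= 1")
  cls <- ifelse(counts >= r$normal_min[1] & counts <= r$normal_max[1],
                "normal",
                ifelse(counts >= r$pathogenic_min[1] &
                         counts <= r$pathogenic_max[1],
                       "pathogenic_expansion", "indeterminate"))
  data.frame(locus = locus, count = counts, class = cls)
}
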
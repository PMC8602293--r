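# Readers and writers for the formats the pipeline touches: VCF 4.2 with
# dialect-mapped INFO keys, TSV evidence tables, BED-plus-columns gene
# panels (0-based half-open on disk, 1-based inclusive internally) and
# per-case JSON reports.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    na.strings = c("NA", "."), stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE,
                    comment.char = "", quote = "")
}

#' Default annotation dialect
#'
#' Maps internal variant fields to the INFO keys (VCF) or column names
#' (TSV) that carry them. Annotation pipelines differ in their key
#' naming, so the mapping is configuration, not code: pass a modified
#' copy to [read_variants()] to ingest another dialect.
#'
#' @return Named character vector `internal_field = on_disk_key`.
#' @export
default_dialect <- function() {
  c(case_id = "CASE", gene = "GENE", hgvs_c = "HGVSC",
    consequence = "CSQ", zygosity = "ZYG",
    af_gnomad = "AF_GNOMAD", af_dbsnp = "AF_DBSNP",
    af_inhouse_eur = "AF_IHEUR", af_inhouse_asian = "AF_IHASIA",
    phylop = "PHYLOP", cadd_phred = "CADD_PHRED", grantham = "GRANTHAM",
    sai_ag = "SAI_AG", sai_al = "SAI_AL", sai_dg = "SAI_DG",
    sai_dl = "SAI_DL",
    prior_allele = "PRIOR", classification = "CLASS",
    hypomorphic = "HYPOMORPH", predicted_event = "PRED_EVENT")
}

#' Read annotated small variants from VCF or TSV
#'
#' VCF files (detected by extension or `##fileformat` header) are parsed
#' with vcfR; annotation values are pulled from INFO keys according to
#' the dialect mapping, one output record per ALT allele. TSV files must
#' carry the same fields as columns (dialect-mapped names or the internal
#' names). Missing annotations become `NA` — never zeros.
#'
#' @param path input file.
#' @param dialect named mapping from internal fields to INFO keys /
#'   column names; see [default_dialect()].
#' @return Validated variant data.frame ([validate_variants()]).
#' @export
read_variants <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop_field("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    (length(first) && startsWith(first, "##fileformat"))
  df <- if (is_vcf) read_variants_vcf(path, dialect)
    else read_variants_tsv(path, dialect)
  validate_variants(df)
}

read_variants_vcf <- function(path, dialect) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  empty <- data.frame(case_id = character(), gene = character(),
                      hgvs_c = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      consequence = character(), zygosity = character())
  if (n == 0) return(empty)
  info <- lapply(names(dialect), function(f)
    suppressWarnings(vcfR::extract.info(vcf, element = dialect[[f]])))
  names(info) <- names(dialect)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    if (is.na(pos))
      stop_field("malformed VCF record ", i, ": field POS is not an integer")
    if (is.na(fix$REF[i]) || is.na(fix$ALT[i]))
      stop_field("malformed VCF record ", i, ": field REF/ALT missing")
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    rec <- data.frame(
      case_id = vcf_info_decode(info$case_id[i] %null_na% NA_character_),
      gene = vcf_info_decode(info$gene[i]),
      hgvs_c = vcf_info_decode(info$hgvs_c[i]),
      chrom = fix$CHROM[i], pos = pos, ref = fix$REF[i],
      alt = rep(alts, each = 1),
      consequence = info$consequence[i], zygosity = info$zygosity[i],
      stringsAsFactors = FALSE)
    for (f in c("af_gnomad", "af_dbsnp", "af_inhouse_eur",
                "af_inhouse_asian", "phylop", "cadd_phred", "grantham",
                "sai_ag", "sai_al", "sai_dg", "sai_dl"))
      rec[[f]] <- suppressWarnings(as.numeric(info[[f]][i]))
    rec$prior_allele <- isTRUE(info$prior_allele[i] %in% c("1", "TRUE"))
    rec$hypomorphic <- isTRUE(info$hypomorphic[i] %in% c("1", "TRUE"))
    rec$classification <- info$classification[i]
    rec$predicted_event <- info$predicted_event[i]
    rows[[i]] <- rec
  }
  do.call(rbind, rows)
}

`%null_na%` <- function(x, y) if (is.null(x)) y else x

# VCF 4.3 percent-encoding for characters reserved in INFO values
vcf_info_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub(" ", "%20", x, fixed = TRUE)
}

vcf_info_decode <- function(x) {
  ifelse(is.na(x), x, vapply(x, function(s) utils::URLdecode(s),
                             character(1), USE.NAMES = FALSE))
}

read_variants_tsv <- function(path, dialect) {
  df <- read_tsv(path)
  # accept either dialect-mapped or internal column names
  for (f in names(dialect)) {
    k <- dialect[[f]]
    if (!f %in% names(df) && k %in% names(df)) names(df)[names(df) == k] <- f
  }
  df
}

#' Write annotated small variants to TSV or VCF 4.2
#'
#' The TSV form writes the internal columns with `.` for missing values.
#' The VCF form emits a minimal VCF 4.2 with all annotations as
#' dialect-mapped INFO keys; reading either file back reproduces the
#' records field-for-field.
#'
#' @param v validated variant table.
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @param dialect mapping used for INFO keys in VCF output.
#' @return `path`, invisibly.
#' @export
write_variants <- function(v, path, format = c("tsv", "vcf"),
                           dialect = default_dialect()) {
  format <- match.arg(format)
  v <- validate_variants(v)
  if (format == "tsv") return(write_tsv(v, path))
  num_type <- c(af_gnomad = "Float", af_dbsnp = "Float",
                af_inhouse_eur = "Float", af_inhouse_asian = "Float",
                phylop = "Float", cadd_phred = "Float", grantham = "Float",
                sai_ag = "Float", sai_al = "Float", sai_dg = "Float",
                sai_dl = "Float")
  hdr <- c("##fileformat=VCFv4.2",
           vapply(names(dialect), function(f) {
             ty <- if (f %in% names(num_type)) "Float"
               else if (f %in% c("prior_allele", "hypomorphic")) "Integer"
               else "String"
             sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
                     dialect[[f]], ty, f)
           }, character(1)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_val <- function(f, i) {
    x <- v[[f]][i]
    if (is.na(x)) return(NULL)
    if (f %in% c("prior_allele", "hypomorphic")) {
      if (!x) return(NULL)
      return(paste0(dialect[[f]], "=1"))
    }
    x <- format(x, scientific = FALSE, trim = TRUE)
    if (is.character(v[[f]])) x <- vcf_info_encode(x)
    paste0(dialect[[f]], "=", x)
  }
  body <- vapply(seq_len(nrow(v)), function(i) {
    kv <- unlist(lapply(names(dialect), fmt_val, i = i))
    paste(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
          paste(kv, collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene panel from a BED-plus-columns file
#'
#' On disk the panel uses BED conventions (0-based half-open intervals):
#' columns chrom, start, end, gene, panel, inheritance, promoter_start,
#' promoter_end (`.` when absent), exon_starts, exon_ends (comma lists).
#' Internally all coordinates are 1-based inclusive (matching g.
#' notation); the conversion is an exact bijection, so writing and
#' re-reading is lossless.
#'
#' @param path BED-plus file; a leading `#`-prefixed header row names the
#'   columns.
#' @return Validated panel data.frame.
#' @export
#' @examples
#' \dontrun{
#' # BED row "chr19 54106453 54133135 PRPF31" becomes start=54106454,
#' # end=54133135 internally.
#' }
read_panel <- function(path) {
  if (!file.exists(path)) stop_field("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "#")) lines <- lines[-1]
  cols <- c("chrom", "start", "end", "gene", "panel", "inheritance",
            "promoter_start", "promoter_end", "exon_starts", "exon_ends")
  if (!length(lines)) {
    out <- data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      panel = character(0), inheritance = character(0),
                      promoter_start = integer(0),
                      promoter_end = integer(0), stringsAsFactors = FALSE)
    out$exons <- list()
    return(validate_panel(out))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < length(cols))
  if (length(bad))
    stop_field("panel line ", bad[1], ": expected ", length(cols),
               " tab-separated fields")
  m <- do.call(rbind, parts)
  df <- data.frame(chrom = m[, 1],
                   start0 = as.integer(m[, 2]), end0 = as.integer(m[, 3]),
                   gene = m[, 4], panel = m[, 5], inheritance = m[, 6],
                   stringsAsFactors = FALSE)
  if (any(df$end0 <= df$start0))
    stop_field("panel contains a zero-length or inverted BED interval")
  int_na <- function(x) suppressWarnings(as.integer(ifelse(x == ".", NA, x)))
  prom_s0 <- int_na(m[, 7]); prom_e0 <- int_na(m[, 8])
  exons <- lapply(seq_len(nrow(m)), function(i) {
    if (m[i, 9] == "." || !nzchar(m[i, 9]))
      return(data.frame(start = integer(0), end = integer(0)))
    s0 <- as.integer(strsplit(m[i, 9], ",")[[1]])
    e0 <- as.integer(strsplit(m[i, 10], ",")[[1]])
    if (length(s0) != length(e0))
      stop_field("panel line ", i, ": exon start/end lists differ in length")
    data.frame(start = s0 + 1L, end = e0)
  })
  out <- data.frame(gene = df$gene, chrom = df$chrom,
                    start = df$start0 + 1L, end = df$end0,
                    panel = df$panel, inheritance = df$inheritance,
                    promoter_start = prom_s0 + 1L, promoter_end = prom_e0,
                    stringsAsFactors = FALSE)
  out$exons <- exons
  validate_panel(out)
}

#' @rdname read_panel
#' @param panel validated panel data.frame (for writing).
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  fmt_int <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- vapply(seq_len(nrow(panel)), function(i) {
    ex <- panel$exons[[i]]
    es <- if (is.null(ex) || nrow(ex) == 0) "."
      else paste(ex$start - 1L, collapse = ",")
    ee <- if (is.null(ex) || nrow(ex) == 0) "."
      else paste(ex$end, collapse = ",")
    paste(panel$chrom[i], panel$start[i] - 1L, panel$end[i], panel$gene[i],
          panel$panel[i], panel$inheritance[i],
          fmt_int(panel$promoter_start[i] - 1L),
          fmt_int(panel$promoter_end[i]), es, ee, sep = "\t")
  }, character(1))
  hdr <- paste0("#", paste(c("chrom", "start", "end", "gene", "panel",
                             "inheritance", "promoter_start",
                             "promoter_end", "exon_starts", "exon_ends"),
                           collapse = "\t"))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a cohort to a directory of standard-format files
#'
#' One file per evidence table: `cases.tsv`, `variants.tsv` (or
#' `variants.vcf`), `alamut.tsv`, `svs.tsv`, `repeats.tsv`,
#' `repeat_ranges.tsv`, `assay_bands.tsv`, `assay_meta.tsv`,
#' `panel.bed` and optionally `tracks.tsv`. [read_cohort()] reproduces
#' the cohort field-for-field.
#'
#' @param cohort an [ird_cohort()].
#' @param dir output directory (created if needed).
#' @param variant_format `"tsv"` or `"vcf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, variant_format = c("tsv", "vcf")) {
  stopifnot(inherits(cohort, "ird_cohort"))
  variant_format <- match.arg(variant_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(cohort$cases, p("cases.tsv"))
  write_variants(cohort$variants,
                 p(paste0("variants.", variant_format)),
                 format = variant_format)
  write_tsv(cohort$alamut, p("alamut.tsv"))
  write_tsv(cohort$svs, p("svs.tsv"))
  write_tsv(cohort$repeats, p("repeats.tsv"))
  write_tsv(cohort$repeat_ranges, p("repeat_ranges.tsv"))
  write_tsv(cohort$assay_bands, p("assay_bands.tsv"))
  write_tsv(cohort$assay_meta, p("assay_meta.tsv"))
  write_panel(cohort$panel, p("panel.bed"))
  if (!is.null(cohort$tracks)) write_tsv(cohort$tracks, p("tracks.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  vfile <- if (file.exists(p("variants.vcf"))) p("variants.vcf")
    else p("variants.tsv")
  tracks <- if (file.exists(p("tracks.tsv"))) read_tsv(p("tracks.tsv"))
    else NULL
  ird_cohort(
    cases = read_tsv(p("cases.tsv")),
    variants = read_variants(vfile),
    panel = read_panel(p("panel.bed")),
    svs = read_tsv(p("svs.tsv")),
    repeats = read_tsv(p("repeats.tsv")),
    repeat_ranges = read_tsv(p("repeat_ranges.tsv")),
    assay_bands = read_tsv(p("assay_bands.tsv")),
    assay_meta = read_tsv(p("assay_meta.tsv")),
    alamut = read_tsv(p("alamut.tsv")),
    tracks = tracks)
}

#' Write a machine-readable per-case report
#'
#' One JSON object per case: status, causal gene, causal alleles with
#' their severity/class labels, rationale tags and the full evidence
#' chain (including gated-out variants, for auditability).
#'
#' @param resolution a `case_resolution` from [resolve_case()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(resolution, path) {
  stopifnot(inherits(resolution, "case_resolution"))
  obj <- list(case_id = resolution$case_id,
              status = resolution$status,
              causal_gene = resolution$causal_gene,
              causal_alleles = resolution$causal_alleles,
              rationale_tags = as.list(resolution$rationale_tags),
              evidence = resolution$evidence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(path)
}
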
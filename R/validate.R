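# Domain tables and their invariants. Each evidence class is carried as a
# plain data.frame with a fixed column contract; validators normalize
# optional columns to NA (never to numeric defaults) and fail loudly on
# contract violations.

#' Consequence vocabulary
#'
#' The accepted effect classes for annotated small variants, in
#' prioritization order (most to least deleterious): nonsense, frameshift,
#' canonical splice site, noncanonical splice site (NCSS), in-frame
#' indel, missense, synonymous, then deep-intronic, UTR and other.
#'
#' @return Character vector of the ten accepted consequence terms.
#' @export
consequence_levels <- function() {
  c("nonsense", "frameshift", "canonical_splice", "ncss", "inframe_indel",
    "missense", "synonymous", "deep_intronic", "utr", "other")
}

classification_levels <- function() {
  c("pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign")
}

#' Phenotype labels of the cohort
#'
#' The clinical diagnosis vocabulary used by case records (one label per
#' cohort phenotype row).
#'
#' @return Character vector of accepted phenotype labels.
#' @export
phenotype_levels <- function() {
  c("Retinitis pigmentosa", "Cone dystrophy", "Rod-cone dystrophy",
    "Cone-rod dystrophy", "Alstrom syndrome", "Bardet-Biedl syndrome",
    "Leber congenital amaurosis", "Macular dystrophy", "Oguchi disease",
    "Central areolar choroidal dystrophy", "Fundus albipunctatus",
    "Usher syndrome type III", "Senior-Loken syndrome", "Nystagmus",
    "Stargardt disease", "Clumped pigmentary retinal dystrophy",
    "Cone-rod dystrophy with progressive neurodegeneration",
    "Retinitis pigmentosa with hypogonadism",
    "Bietti crystalline corneoretinal dystrophy",
    "Congenital stationary night blindness", "Achromatopsia")
}

alamut_algorithms <- function() {
  c("SSFL", "MaxEntScan", "GeneSplicer", "HSF", "NNSPLICE")
}

col_or_na <- function(df, cn) {
  if (cn %in% names(df)) df[[cn]] else rep(NA, nrow(df))
}

empty_variants <- function() {
  data.frame(case_id = character(), gene = character(),
             hgvs_c = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(),
             consequence = character(), zygosity = character(),
             stringsAsFactors = FALSE)
}

variant_columns <- function() {
  c("case_id", "gene", "hgvs_c", "chrom", "pos", "ref", "alt",
    "consequence", "zygosity",
    "af_gnomad", "af_dbsnp", "af_inhouse_eur", "af_inhouse_asian",
    "phylop", "cadd_phred", "grantham",
    "sai_ag", "sai_al", "sai_dg", "sai_dl",
    "prior_allele", "classification", "hypomorphic", "predicted_event")
}

# fill optional columns with NA and coerce base types
normalize_variants <- function(df) {
  need <- c("case_id", "gene", "hgvs_c", "chrom", "pos", "ref", "alt",
            "consequence", "zygosity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("variant table missing required column(s): ",
               paste(miss, collapse = ", "))
  num <- c("af_gnomad", "af_dbsnp", "af_inhouse_eur", "af_inhouse_asian",
           "phylop", "cadd_phred", "grantham",
           "sai_ag", "sai_al", "sai_dg", "sai_dl")
  for (cn in num)
    df[[cn]] <- as.numeric(col_or_na(df, cn))
  df$prior_allele <- as.logical(col_or_na(df, "prior_allele"))
  df$prior_allele[is.na(df$prior_allele)] <- FALSE
  df$hypomorphic <- as.logical(col_or_na(df, "hypomorphic"))
  df$hypomorphic[is.na(df$hypomorphic)] <- FALSE
  df$classification <- as.character(col_or_na(df, "classification"))
  df$predicted_event <- as.character(col_or_na(df, "predicted_event"))
  df$pos <- as.integer(df$pos)
  for (cn in c("case_id", "gene", "hgvs_c", "chrom", "ref", "alt",
               "consequence", "zygosity"))
    df[[cn]] <- as.character(df[[cn]])
  rownames(df) <- NULL
  df[variant_columns()]
}

#' Validate a table of annotated small variants
#'
#' Checks the record invariants: positions >= 1, nonempty REF/ALT, a known
#' consequence term, zygosity het/hom, allele frequencies within \[0, 1\],
#' in-silico scores within their documented ranges (PhyloP -14.1..6.4,
#' CADD-PHRED 1..99, Grantham 0..215), SpliceAI deltas within \[0, 1\] and
#' a classification present wherever `prior_allele` is set. Missing
#' annotations stay `NA`; no numeric default is ever imputed.
#'
#' @param df data.frame of variant records (see [variant_columns()]).
#' @return The normalized data.frame, invisibly usable downstream.
#' @export
validate_variants <- function(df) {
  df <- normalize_variants(df)
  if (nrow(df) == 0) return(df)
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad)) stop_field("variant row ", bad[1], ": pos must be >= 1")
  bad <- which(!nzchar(df$ref) | !nzchar(df$alt) | is.na(df$ref) | is.na(df$alt))
  if (length(bad)) stop_field("variant row ", bad[1], ": ref/alt must be nonempty")
  unknown <- setdiff(unique(df$consequence), consequence_levels())
  if (length(unknown))
    stop_field("unknown consequence term(s): ",
               paste(unknown, collapse = ", "),
               "; accepted vocabulary: ",
               paste(consequence_levels(), collapse = ", "))
  if (!all(df$zygosity %in% c("het", "hom")))
    stop_field("zygosity must be 'het' or 'hom'")
  for (cn in c("af_gnomad", "af_dbsnp", "af_inhouse_eur", "af_inhouse_asian")) {
    v <- df[[cn]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop_field(cn, " must lie in [0, 1] when present")
  }
  rng <- list(phylop = c(-14.1, 6.4), cadd_phred = c(1, 99),
              grantham = c(0, 215),
              sai_ag = c(0, 1), sai_al = c(0, 1),
              sai_dg = c(0, 1), sai_dl = c(0, 1))
  for (cn in names(rng)) {
    v <- df[[cn]]
    if (any(!is.na(v) & (v < rng[[cn]][1] | v > rng[[cn]][2])))
      stop_field(cn, " outside documented range [",
                 rng[[cn]][1], ", ", rng[[cn]][2], "]")
  }
  cls <- df$classification
  if (any(!is.na(cls) & !cls %in% classification_levels()))
    stop_field("classification must be one of: ",
               paste(classification_levels(), collapse = ", "))
  if (any(df$prior_allele & is.na(cls)))
    stop_field("prior_allele implies a classification is present")
  df
}

#' Validate a structural-variant call table
#'
#' @param df data.frame with columns case_id, chrom, start, end, svtype
#'   (del/dup/inv), zygosity (het/hom) and optional left_flank /
#'   right_flank junction sequences over A,C,G,T,N.
#' @return The normalized data.frame.
#' @export
validate_svs <- function(df) {
  need <- c("case_id", "chrom", "start", "end", "svtype", "zygosity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("SV table missing column(s): ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  for (cn in c("left_flank", "right_flank"))
    df[[cn]] <- as.character(col_or_na(df, cn))
  if (nrow(df) == 0) return(df[c(need, "left_flank", "right_flank")])
  if (any(df$end < df$start)) stop_field("SV end must be >= start")
  if (!all(df$svtype %in% c("del", "dup", "inv")))
    stop_field("svtype must be del, dup or inv")
  if (!all(df$zygosity %in% c("het", "hom")))
    stop_field("SV zygosity must be het or hom")
  for (cn in c("left_flank", "right_flank")) {
    s <- df[[cn]]
    ok <- is.na(s) | grepl("^[ACGTN]*$", s)
    if (!all(ok)) stop_field(cn, " must be DNA over {A,C,G,T,N}")
  }
  rownames(df) <- NULL
  df[c(need, "left_flank", "right_flank")]
}

#' Validate repeat genotypes and the repeat-locus range table
#'
#' `validate_repeats()` checks per-allele repeat counts >= 1;
#' `validate_repeat_ranges()` checks that each locus has a normal range
#' strictly below its pathogenic range.
#'
#' @param df data.frame: for genotypes case_id, locus, allele1, allele2;
#'   for ranges locus, normal_min, normal_max, pathogenic_min,
#'   pathogenic_max.
#' @return The normalized data.frame.
#' @export
validate_repeats <- function(df) {
  need <- c("case_id", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("repeat table missing column(s): ", paste(miss, collapse = ", "))
  df$allele1 <- as.integer(df$allele1); df$allele2 <- as.integer(df$allele2)
  if (nrow(df) && any(c(df$allele1, df$allele2) < 1L))
    stop_field("repeat counts must be >= 1")
  rownames(df) <- NULL
  df[need]
}

#' @rdname validate_repeats
#' @export
validate_repeat_ranges <- function(df) {
  need <- c("locus", "normal_min", "normal_max", "pathogenic_min",
            "pathogenic_max")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("repeat range table missing column(s): ",
               paste(miss, collapse = ", "))
  for (cn in need[-1]) df[[cn]] <- as.integer(df[[cn]])
  if (nrow(df) && any(df$normal_max >= df$pathogenic_min))
    stop_field("normal_max must be below pathogenic_min for every locus")
  rownames(df) <- NULL
  df[need]
}

#' Validate splice-assay band and metadata tables
#'
#' Band tables carry one lane per row: the construct (`wt` or `mut`), the
#' fragment length in nucleotides, a nonnegative gel intensity in
#' arbitrary units, and an `ignore` flag for heteroduplex/artifact lanes
#' excluded from quantification. The metadata table carries, per assayed
#' variant, the wild-type fragment length and (optionally) the hypothesized
#' splice event.
#'
#' @param df band table (gene, hgvs_c, construct, fragment_length_nt,
#'   intensity, ignore) or metadata table (gene, hgvs_c,
#'   wt_fragment_length, event_kind, event_size).
#' @return The normalized data.frame.
#' @export
validate_assay_bands <- function(df) {
  need <- c("gene", "hgvs_c", "construct", "fragment_length_nt", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("assay band table missing column(s): ",
               paste(miss, collapse = ", "))
  df$fragment_length_nt <- as.integer(df$fragment_length_nt)
  df$intensity <- as.numeric(df$intensity)
  df$ignore <- as.logical(col_or_na(df, "ignore"))
  df$ignore[is.na(df$ignore)] <- FALSE
  if (nrow(df)) {
    if (!all(df$construct %in% c("wt", "mut")))
      stop_field("assay construct must be 'wt' or 'mut'")
    if (any(df$intensity < 0)) stop_field("lane intensities must be >= 0")
    if (any(df$fragment_length_nt < 1L))
      stop_field("fragment lengths must be positive")
  }
  rownames(df) <- NULL
  df[c(need, "ignore")]
}

#' @rdname validate_assay_bands
#' @export
validate_assay_meta <- function(df) {
  need <- c("gene", "hgvs_c", "wt_fragment_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("assay metadata missing column(s): ",
               paste(miss, collapse = ", "))
  df$wt_fragment_length <- as.integer(df$wt_fragment_length)
  df$event_kind <- as.character(col_or_na(df, "event_kind"))
  df$event_size <- as.integer(col_or_na(df, "event_size"))
  if (nrow(df)) {
    if (any(df$wt_fragment_length < 1L))
      stop_field("wt_fragment_length must be positive")
    known <- c("pseudoexon_insertion", "exon_elongation", "exon_skipping",
               "partial_exon_deletion")
    if (any(!is.na(df$event_kind) & !df$event_kind %in% known))
      stop_field("event_kind must be one of: ", paste(known, collapse = ", "))
  }
  rownames(df) <- NULL
  df[c(need, "event_kind", "event_size")]
}

#' Validate an Alamut algorithm score-pair table
#'
#' One row per (variant, algorithm, site): wild-type and mutant scores on
#' the algorithm's own scale (scale maximum 100 for SSFL/HSF, 1 for
#' NNSPLICE, algorithm-documented otherwise).
#'
#' @param df data.frame with gene, hgvs_c, algorithm, site_kind
#'   (donor/acceptor), wt_score, mut_score, scale_max.
#' @return The normalized data.frame.
#' @export
validate_alamut <- function(df) {
  need <- c("gene", "hgvs_c", "algorithm", "site_kind", "wt_score",
            "mut_score", "scale_max")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("alamut table missing column(s): ", paste(miss, collapse = ", "))
  df$wt_score <- as.numeric(df$wt_score)
  df$mut_score <- as.numeric(df$mut_score)
  df$scale_max <- as.numeric(df$scale_max)
  if (nrow(df)) {
    if (!all(df$algorithm %in% alamut_algorithms()))
      stop_field("algorithm must be one of: ",
                 paste(alamut_algorithms(), collapse = ", "))
    if (!all(df$site_kind %in% c("donor", "acceptor")))
      stop_field("site_kind must be donor or acceptor")
    if (any(stats::na.omit(c(df$wt_score, df$mut_score)) < 0))
      stop_field("alamut scores must be >= 0")
  }
  rownames(df) <- NULL
  df[need]
}

#' Validate a gene panel
#'
#' Panel entries use 1-based inclusive internal coordinates. Exons are a
#' list-column of data.frames (start, end); each exon must lie within the
#' gene span and exon intervals must be well-ordered. Duplicate gene names
#' with overlapping spans are rejected.
#'
#' @param df panel data.frame: gene, chrom, start, end, panel
#'   (ird/ciliopathy/other), inheritance (AR/AD/AD_incomplete_penetrance/
#'   XL), promoter_start, promoter_end (NA when absent), exons list-column.
#' @return The normalized data.frame.
#' @export
validate_panel <- function(df) {
  need <- c("gene", "chrom", "start", "end", "panel", "inheritance", "exons")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("panel missing column(s): ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  for (cn in c("promoter_start", "promoter_end"))
    df[[cn]] <- as.integer(col_or_na(df, cn))
  if (nrow(df) == 0) return(df)
  if (any(df$end < df$start)) stop_field("panel gene end must be >= start")
  if (!all(df$panel %in% c("ird", "ciliopathy", "other")))
    stop_field("panel must be ird, ciliopathy or other")
  if (!all(df$inheritance %in% c("AR", "AD", "AD_incomplete_penetrance", "XL")))
    stop_field("inheritance must be AR, AD, AD_incomplete_penetrance or XL")
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) next
    if (any(ex$end < ex$start))
      stop_field("gene ", df$gene[i], ": exon end < start")
    if (any(ex$start < df$start[i] | ex$end > df$end[i]))
      stop_field("gene ", df$gene[i], ": exons must lie within the gene span")
    if (nrow(ex) > 1 && any(diff(ex$start) <= 0))
      stop_field("gene ", df$gene[i], ": exon intervals must be well-ordered")
  }
  # overlapping duplicates
  dup <- unique(df$gene[duplicated(df$gene)])
  for (g in dup) {
    rows <- df[df$gene == g, ]
    if (nrow(rows) > 1) {
      o <- order(rows$start)
      rows <- rows[o, ]
      same_chr <- rows$chrom[-1] == rows$chrom[-nrow(rows)]
      ovl <- rows$start[-1] <= rows$end[-nrow(rows)]
      if (any(same_chr & ovl))
        stop_field("panel contains overlapping duplicate entries for gene ", g)
    }
  }
  rownames(df) <- NULL
  df
}

validate_cases <- function(df) {
  need <- c("case_id", "phenotype", "prior_method")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("case table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$case_id))
    stop_field("case_id must be unique within a cohort")
  bad <- setdiff(unique(df$phenotype), phenotype_levels())
  if (length(bad))
    stop_field("unknown phenotype label(s): ", paste(bad, collapse = "; "))
  if (!all(df$prior_method %in% c("TCS", "WES")))
    stop_field("prior_method must be TCS or WES")
  rownames(df) <- NULL
  df[need]
}

validate_tracks <- function(df) {
  if (is.null(df)) return(NULL)
  need <- c("case_id", "chrom", "pos", "het")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("genotype track missing column(s): ", paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos); df$het <- as.logical(df$het)
  rownames(df) <- NULL
  df[need]
}

#' Assemble a cohort object
#'
#' Bundles all evidence tables of a cohort into a single validated
#' container, the unit on which prioritization and resolution operate.
#' Every component is checked against its invariants on construction.
#'
#' @param cases case table (case_id, phenotype, prior_method).
#' @param variants annotated small-variant table ([validate_variants()]).
#' @param panel gene panel ([validate_panel()]).
#' @param svs structural-variant calls (optional).
#' @param repeats repeat genotypes (optional).
#' @param repeat_ranges repeat-locus normal/pathogenic ranges (optional).
#' @param assay_bands,assay_meta splice-assay band tables and metadata
#'   (optional).
#' @param alamut Alamut algorithm score pairs (optional).
#' @param tracks biallelic genotype tracks for ROH scanning (optional).
#' @return A list of class `ird_cohort`.
#' @export
ird_cohort <- function(cases, variants, panel,
                       svs = NULL, repeats = NULL, repeat_ranges = NULL,
                       assay_bands = NULL, assay_meta = NULL,
                       alamut = NULL, tracks = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  obj <- structure(list(
    cases = validate_cases(cases),
    variants = validate_variants(variants %||% empty_variants()),
    panel = validate_panel(panel),
    svs = validate_svs(svs %||% empty(c("case_id", "chrom", "start", "end",
                                        "svtype", "zygosity"))),
    repeats = validate_repeats(repeats %||% empty(c("case_id", "locus",
                                                    "allele1", "allele2"))),
    repeat_ranges = validate_repeat_ranges(
      repeat_ranges %||% empty(c("locus", "normal_min", "normal_max",
                                 "pathogenic_min", "pathogenic_max"))),
    assay_bands = validate_assay_bands(
      assay_bands %||% empty(c("gene", "hgvs_c", "construct",
                               "fragment_length_nt", "intensity"))),
    assay_meta = validate_assay_meta(
      assay_meta %||% empty(c("gene", "hgvs_c", "wt_fragment_length"))),
    alamut = validate_alamut(
      alamut %||% empty(c("gene", "hgvs_c", "algorithm", "site_kind",
                          "wt_score", "mut_score", "scale_max"))),
    tracks = validate_tracks(tracks)
  ), class = "ird_cohort")
  obj
}

#' @export
print.ird_cohort <- function(x, ...) {
  cat("IRD cohort:", nrow(x$cases), "cases\n")
  cat("  small variants:", nrow(x$variants),
      "| SVs:", nrow(x$svs),
      "| repeat genotypes:", nrow(x$repeats), "\n")
  cat("  assays:", nrow(x$assay_meta),
      "| panel genes:", nrow(x$panel), "\n")
  invisible(x)
}
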
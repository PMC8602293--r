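# Deterministic cohort fixture transcribed from the published solved-case
# table, the cohort phenotype table and the Results-text assay outcomes.
# Only raw evidence is encoded (genotypes, band tables, SV coordinates,
# repeat counts, score triggers); solved/unsolved status labels are never
# part of the fixture inputs. Gene coordinates are a self-consistent
# miniature annotation (invented, except the published chromosome-19
# deletion breakpoints); positions inside genes are placeholders because
# no computed quantity depends on them.

#' Default miniature gene panel
#'
#' IRD and ciliopathy panel genes covering all fixture genotypes, the two
#' non-IRD genes needed to interpret the chromosome-19 deletion (TFPT,
#' NDUFA3, panel class `other`) and decoy genes. Coordinates are an
#' invented self-consistent annotation except the chromosome-19 region,
#' which matches the published deletion breakpoints (g.54106454-54133135).
#'
#' @return Validated panel data.frame.
#' @export
default_panel <- function() {
  mk <- function(gene, chrom, start, inheritance, panel = "ird",
                 len = 60000L, n_exons = 10L, exon_len = 150L) {
    gap <- (len - n_exons * exon_len) %/% (n_exons + 1L)
    ex_start <- start + gap + (seq_len(n_exons) - 1L) * (gap + exon_len)
    data.frame(gene = gene, chrom = chrom, start = start,
               end = start + len - 1L, panel = panel,
               inheritance = inheritance,
               promoter_start = start - 600L, promoter_end = start - 1L,
               exons = I(list(data.frame(start = ex_start,
                                         end = ex_start + exon_len - 1L))),
               stringsAsFactors = FALSE)
  }
  rows <- list(
    mk("ABCA4", "chr1", 94000000L, "AR"),
    mk("RPE65", "chr1", 68000000L, "AR"),
    mk("USH2A", "chr1", 215000000L, "AR"),
    mk("FAM161A", "chr2", 62000000L, "AR"),
    mk("PCARE", "chr2", 29000000L, "AR"),
    mk("ATXN7", "chr3", 63000000L, "AD"),
    mk("RHO", "chr3", 129000000L, "AD"),
    mk("CYP4V2", "chr4", 187000000L, "AR"),
    mk("PDE6B", "chr4", 600000L, "AR"),
    mk("GRM6", "chr5", 178000000L, "AR"),
    mk("PDE6A", "chr5", 149000000L, "AR"),
    mk("EYS", "chr6", 64000000L, "AR"),
    mk("HGSNAT", "chr8", 43000000L, "AR"),
    mk("CEP78", "chr9", 81000000L, "AR"),
    mk("CDHR1", "chr10", 85000000L, "AR"),
    mk("CEP290", "chr12", 88000000L, "AR", panel = "ciliopathy"),
    mk("RLBP1", "chr15", 89000000L, "AR"),
    mk("RGS9BP", "chr19", 33000000L, "AR"),
    mk("C21ORF2", "chr21", 45000000L, "AR")
  )
  # chromosome-19 deletion region: PRPF31 + TFPT inside the published
  # breakpoints, NDUFA3 downstream with only its promoter inside
  prpf31 <- mk("PRPF31", "chr19", 54110000L, "AD_incomplete_penetrance",
               len = 10000L, n_exons = 8L, exon_len = 120L)
  tfpt <- mk("TFPT", "chr19", 54122000L, "AR", panel = "other",
             len = 4000L, n_exons = 5L, exon_len = 120L)
  ndufa3 <- mk("NDUFA3", "chr19", 54134000L, "AR", panel = "other",
               len = 2000L, n_exons = 4L, exon_len = 100L)
  ndufa3$promoter_start <- 54132800L
  ndufa3$promoter_end <- 54133400L
  # RPGRIP1: explicit exons so that a ~3.5-kb deletion removes exactly
  # one 101-bp exon (frameshift: 101 mod 3 != 0)
  rpgrip1 <- data.frame(
    gene = "RPGRIP1", chrom = "chr14", start = 21700000L, end = 21800000L,
    panel = "ird", inheritance = "AR",
    promoter_start = 21699400L, promoter_end = 21699999L,
    exons = I(list(data.frame(
      start = c(21705000L, 21720000L, 21745000L, 21775000L, 21780000L,
                21790000L),
      end = c(21705150L, 21720150L, 21745150L, 21775120L, 21780100L,
              21790140L)))),
    stringsAsFactors = FALSE)
  validate_panel(do.call(rbind, c(rows, list(prpf31, tfpt, ndufa3,
                                             rpgrip1))))
}

#' Default repeat-locus range table
#'
#' ATXN7 wild-type (3-19 CAG) and pathogenic (37-460) ranges, plus two
#' synthetic placeholder loci representing the wider screened catalog.
#'
#' @return Validated range table.
#' @export
default_repeat_ranges <- function() {
  validate_repeat_ranges(data.frame(
    locus = c("ATXN7", "SYN_STR_A", "SYN_STR_B"),
    normal_min = c(3L, 5L, 6L), normal_max = c(19L, 30L, 25L),
    pathogenic_min = c(37L, 45L, 40L),
    pathogenic_max = c(460L, 200L, 180L)))
}

fixture_phenotypes <- function() {
  ph <- phenotype_levels()
  named <- c(
    "Pt-1" = "Stargardt disease", "Pt-2" = "Stargardt disease",
    "Pt-3" = "Stargardt disease",
    "Pt-4" = "Cone-rod dystrophy with progressive neurodegeneration",
    "Pt-5" = "Retinitis pigmentosa", "Pt-6" = "Retinitis pigmentosa",
    "Pt-7" = "Retinitis pigmentosa", "Pt-8" = "Alstrom syndrome",
    "Pt-9" = "Retinitis pigmentosa", "Pt-10" = "Retinitis pigmentosa",
    "Pt-11" = "Cone-rod dystrophy", "Pt-12" = "Rod-cone dystrophy",
    "Pt-13" = "Retinitis pigmentosa", "Pt-14" = "Oguchi disease",
    "Pt-15" = "Retinitis pigmentosa", "Pt-16" = "Retinitis pigmentosa",
    "Pt-17" = "Retinitis pigmentosa", "Pt-18" = "Retinitis pigmentosa",
    "Pt-19" = "Retinitis pigmentosa", "Pt-20" = "Retinitis pigmentosa",
    "Pt-21" = "Cone-rod dystrophy", "Pt-22" = "Leber congenital amaurosis",
    "Pt-23" = "Retinitis pigmentosa", "Pt-24" = "Retinitis pigmentosa",
    "Pt-27" = "Stargardt disease", "Pt-28" = "Stargardt disease",
    "Pt-29" = "Stargardt disease", "Pt-30" = "Stargardt disease",
    "Pt-52" = "Bietti crystalline corneoretinal dystrophy",
    "Pt-61" = "Retinitis pigmentosa", "Pt-65" = "Fundus albipunctatus")
  # remaining per-phenotype counts for the filler cases
  fill_counts <- c("Retinitis pigmentosa" = 38L, "Cone dystrophy" = 3L,
                   "Rod-cone dystrophy" = 2L, "Cone-rod dystrophy" = 7L,
                   "Bardet-Biedl syndrome" = 1L,
                   "Leber congenital amaurosis" = 1L,
                   "Macular dystrophy" = 9L,
                   "Central areolar choroidal dystrophy" = 1L,
                   "Usher syndrome type III" = 1L,
                   "Senior-Loken syndrome" = 1L, "Nystagmus" = 1L,
                   "Clumped pigmentary retinal dystrophy" = 1L,
                   "Retinitis pigmentosa with hypogonadism" = 1L,
                   "Congenital stationary night blindness" = 1L,
                   "Achromatopsia" = 1L)
  stopifnot(all(names(fill_counts) %in% ph))
  list(named = named, fill = rep(names(fill_counts), fill_counts))
}

#' Build the deterministic cohort fixture
#'
#' A 100-case cohort whose phenotype histogram matches the published
#' cohort table and whose evidence (small-variant genotypes with
#' frequencies, scores and splice-prediction triggers; two structural
#' variants with breakpoints; one repeat expansion; eleven splice-assay
#' band tables) is transcribed from the published solved-case table and
#' Results text. Filler cases carry non-resolving evidence constructed to
#' fail exactly one gate each (frequency, score count, or delta
#' threshold), exercising every rejection path. The fixture is
#' byte-identical across builds (no randomness) and carries no
#' solved-status labels.
#'
#' @return An [ird_cohort()].
#' @export
build_cohort_fixture <- function() {
  panel <- default_panel()
  gpos <- function(gene, k) {
    i <- match(gene, panel$gene)
    panel$start[i] + 500L * k
  }
  ph <- fixture_phenotypes()

  v <- list()
  vr <- function(case_id, gene, hgvs, consequence, zygosity,
                 af_gnomad = NA, phylop = NA, cadd = NA, grantham = NA,
                 sai = c(NA, NA, NA, NA), prior = FALSE, class = NA,
                 hypo = FALSE, event = NA,
                 k = sum(utf8ToInt(hgvs)) %% 100L + 1L,
                 ref = "A", alt = "T") {
    v[[length(v) + 1L]] <<- data.frame(
      case_id = case_id, gene = gene, hgvs_c = hgvs,
      chrom = panel$chrom[match(gene, panel$gene)], pos = gpos(gene, k),
      ref = ref, alt = alt, consequence = consequence, zygosity = zygosity,
      af_gnomad = af_gnomad, af_dbsnp = NA_real_,
      af_inhouse_eur = NA_real_, af_inhouse_asian = NA_real_,
      phylop = phylop, cadd_phred = cadd, grantham = grantham,
      sai_ag = sai[1], sai_al = sai[2], sai_dg = sai[3], sai_dl = sai[4],
      prior_allele = prior, classification = class, hypomorphic = hypo,
      predicted_event = event, stringsAsFactors = FALSE)
  }

  # -- solved-case genotypes (evidence only) --------------------------------
  vr("Pt-1", "ABCA4", "c.6079C>T", "missense", "het", 1e-4, 4.2, 28, 98,
     prior = TRUE, class = "pathogenic")
  vr("Pt-1", "ABCA4", "c.5196+1137G>A", "deep_intronic", "het", 2e-5,
     sai = c(0.25, 0, 0, 0), class = "pathogenic",
     event = "pseudoexon_insertion")
  vr("Pt-2", "ABCA4", "c.6743T>C", "missense", "het", 5e-5, 5.0, 26, 155,
     prior = TRUE, class = "pathogenic")
  vr("Pt-2", "ABCA4", "c.4539+2028C>T", "deep_intronic", "het", 1e-5,
     sai = c(0.22, 0, 0, 0), class = "pathogenic",
     event = "pseudoexon_insertion")
  vr("Pt-3", "ABCA4", "c.5603A>T", "missense", "het", 0.043, 2.9, 16, 94,
     prior = TRUE, class = "pathogenic", hypo = TRUE)
  vr("Pt-3", "ABCA4", "c.286A>C", "missense", "het", 3e-5, 3.1, 24, 90,
     class = "likely_pathogenic")
  vr("Pt-5", "C21ORF2", "c.218G>C", "missense", "het", 2e-4, 4.0, 25, 103,
     class = "pathogenic")
  vr("Pt-5", "C21ORF2", "c.76T>C", "missense", "het", 8e-5, 3.6, 23, 101,
     class = "pathogenic")
  vr("Pt-6", "C21ORF2", "c.218G>C", "missense", "hom", 2e-4, 4.0, 25, 103,
     class = "pathogenic")
  vr("Pt-7", "CDHR1", "c.783G>A", "ncss", "hom", 0.003052,
     sai = c(0, 0, 0, 0.35), event = "exon_skipping")
  vr("Pt-8", "CEP78", "c.1033G>T", "nonsense", "hom", NA)
  vr("Pt-9", "EYS", "c.[3906C>A;9468T>A]", "nonsense", "het", 4e-5,
     prior = TRUE, class = "pathogenic")
  vr("Pt-9", "EYS", "c.5644+70912A>G", "deep_intronic", "het", NA,
     sai = c(0.57, 0, 0, 0), event = "pseudoexon_insertion")
  vr("Pt-10", "EYS", "c.403_423delinsCTTTT", "frameshift", "het", NA,
     prior = TRUE, class = "pathogenic", ref = "ACGTACGTACGTACGTACGTA",
     alt = "CTTTT")
  vr("Pt-10", "EYS", "c.539C>A", "nonsense", "het", 6e-5)
  vr("Pt-11", "EYS", "c.9468T>A", "nonsense", "hom", 4e-5)
  vr("Pt-12", "EYS", "c.1660T>A", "missense", "het", 9e-5, 4.4, 27, 112,
     prior = TRUE, class = "pathogenic")
  vr("Pt-12", "EYS", "c.5044G>T", "missense", "het", 2e-5, 5.9, 29, 101,
     class = "vus")
  vr("Pt-13", "FAM161A", "c.1753_1756del", "frameshift", "hom", 1e-4,
     ref = "AAGAA", alt = "A")
  vr("Pt-14", "GRM6", "c.1732C>T", "missense", "het", 1.2e-4, 4.8, 29, 180,
     prior = TRUE, class = "pathogenic")
  vr("Pt-14", "GRM6", "c.1355-587dup", "deep_intronic", "het", 1e-4,
     sai = c(0.30, 0, 0.11, 0), event = "pseudoexon_insertion",
     ref = "G", alt = "GG")
  vr("Pt-15", "HGSNAT", "c.1843G>A", "missense", "hom", 0.008, 2.9, 21, 58,
     class = "pathogenic", hypo = TRUE)
  vr("Pt-16", "HGSNAT", "c.1030C>T", "missense", "het", 7e-5, 3.9, 26, 180,
     class = "likely_pathogenic")
  vr("Pt-16", "HGSNAT", "c.1843G>A", "missense", "het", 0.008, 2.9, 21, 58,
     class = "pathogenic", hypo = TRUE)
  vr("Pt-17", "HGSNAT", "c.1843G>A", "missense", "het", 0.008, 2.9, 21, 58,
     prior = TRUE, class = "pathogenic", hypo = TRUE)
  vr("Pt-17", "HGSNAT", "c.493+5G>A", "ncss", "het", NA,
     sai = c(0, 0, 0, 0.48), event = "exon_skipping")
  vr("Pt-18", "HGSNAT", "c.1843G>A", "missense", "hom", 0.008, 2.9, 21, 58,
     class = "pathogenic", hypo = TRUE)
  vr("Pt-19", "HGSNAT", "c.1622C>T", "missense", "het", 5e-5, 3.2, 24, 145,
     class = "likely_pathogenic")
  vr("Pt-19", "HGSNAT", "c.1843G>A", "missense", "het", 0.008, 2.9, 21, 58,
     class = "pathogenic", hypo = TRUE)
  vr("Pt-20", "PCARE", "c.3604C>T", "nonsense", "het", 3e-5,
     prior = TRUE, class = "pathogenic")
  vr("Pt-20", "PCARE", "c.3099_3100insCAGG", "frameshift", "het", NA,
     ref = "T", alt = "TCAGG")
  vr("Pt-21", "RGS9BP", "c.583T>G", "missense", "hom", 1e-4, 3.4, 22, 99,
     class = "pathogenic")
  vr("Pt-22", "CEP290", "c.1079G>A", "missense", "het", 2e-4, 3.5, 23, 125,
     prior = TRUE, class = "likely_pathogenic")
  vr("Pt-22", "PDE6A", "c.2053G>A", "missense", "het", 3e-4, 3.0, 21, 84,
     prior = TRUE, class = "likely_pathogenic")
  vr("Pt-22", "RPE65", "c.676G>A", "missense", "het", 4e-4, 2.8, 19, 96,
     prior = TRUE, class = "likely_pathogenic")
  vr("Pt-24", "PCARE", "c.2756_2757del", "frameshift", "het", 2e-5,
     prior = TRUE, class = "pathogenic", ref = "CTT", alt = "C")
  vr("Pt-24", "USH2A", "c.4758+3A>G", "ncss", "het", 1e-5,
     sai = c(0, 0, 0.52, 0), event = "exon_elongation")
  vr("Pt-24", "USH2A", "c.784+14389G>T", "deep_intronic", "het", NA,
     sai = c(0.64, 0, 0, 0), event = "pseudoexon_insertion")

  # -- monoallelic cases whose candidate showed no splice defect -----------
  vr("Pt-27", "ABCA4", "c.5882G>A", "missense", "het", 4e-3, 3.3, 24, 97,
     prior = TRUE, class = "pathogenic")
  vr("Pt-27", "ABCA4", "c.6148-89G>A", "deep_intronic", "het", NA,
     sai = c(0, 0, 0.12, 0), event = "cryptic_site_gain")
  for (pt in c("Pt-28", "Pt-29", "Pt-30")) {
    vr(pt, "ABCA4", paste0("c.634C>T"), "missense", "het", 1e-3, 3.0, 22, 90,
       prior = TRUE, class = "pathogenic")
    vr(pt, "ABCA4", "c.5460+1315_5460+1317delinsTA", "deep_intronic", "het",
       NA, event = "cryptic_site_gain", ref = "CAT", alt = "TA")
  }
  vr("Pt-52", "CYP4V2", "c.992A>C", "missense", "het", 6e-4, 3.7, 24, 110,
     prior = TRUE, class = "pathogenic")
  vr("Pt-52", "CYP4V2", "c.214+879_214+882delinsG", "deep_intronic", "het",
     NA, event = "cryptic_site_gain", ref = "TTTT", alt = "G")
  vr("Pt-61", "PDE6B", "c.1540C>T", "nonsense", "het", 8e-5,
     prior = TRUE, class = "pathogenic")
  vr("Pt-61", "PDE6B", "c.469-776C>G", "deep_intronic", "het", 5e-4,
     sai = c(0.04, 0, 0, 0), event = "cryptic_site_gain")
  vr("Pt-65", "RLBP1", "c.700C>T", "missense", "het", 1e-4, 4.1, 26, 140,
     prior = TRUE, class = "pathogenic")
  vr("Pt-65", "RLBP1", "c.525+425_525+433delinsATA", "deep_intronic", "het",
     NA, event = "cryptic_site_gain", ref = "ACGTACGTA", alt = "ATA")

  # -- filler cases: each fails exactly one gate ----------------------------
  named_ids <- names(ph$named)
  filler_ids <- setdiff(paste0("Pt-", 1:100), named_ids)
  filler_ids <- filler_ids[order(as.integer(sub("Pt-", "", filler_ids)))]
  filler_genes <- c("CEP290", "PDE6A", "RPE65", "EYS", "USH2A", "ABCA4")
  for (i in seq_along(filler_ids)) {
    id <- filler_ids[i]
    g <- filler_genes[(i - 1L) %% length(filler_genes) + 1L]
    mode <- (i - 1L) %% 3L
    if (mode == 0L) {
      vr(id, g, sprintf("c.%d00C>T", 10 + i), "nonsense", "het", 0.02)
    } else if (mode == 1L) {
      vr(id, g, sprintf("c.%d01G>A", 10 + i), "missense", "het", 5e-4,
         3.0, 8, 40)
    } else {
      vr(id, g, sprintf("c.%d02-77A>G", 10 + i), "deep_intronic", "het",
         5e-4, sai = c(0.01, 0, 0, 0))
    }
  }
  variants <- do.call(rbind, v)

  # -- SVs ------------------------------------------------------------------
  mh <- "ACGGTTAACGGT" # constructed 12-bp junction microhomology
  svs <- data.frame(
    case_id = c("Pt-22", "Pt-23"),
    chrom = c("chr14", "chr19"),
    start = c(21776900L, 54106454L),
    end = c(21780423L, 54133135L),
    svtype = c("del", "del"),
    zygosity = c("hom", "het"),
    left_flank = c(paste0("GATTCCAT", mh), NA),
    right_flank = c(paste0(mh, "TTGGACGA"), NA),
    stringsAsFactors = FALSE)

  # -- repeats --------------------------------------------------------------
  repeats <- data.frame(
    case_id = c("Pt-4", "Pt-25", "Pt-33"),
    locus = "ATXN7",
    allele1 = c(70L, 10L, 15L),
    allele2 = c(12L, 12L, 9L), stringsAsFactors = FALSE)

  # -- Alamut score pairs (cryptic donor gains) -----------------------------
  alamut <- data.frame(
    gene = c("ABCA4", "ABCA4",
             "ABCA4", "ABCA4",
             "CYP4V2", "CYP4V2",
             "RLBP1", "RLBP1"),
    hgvs_c = c("c.6148-89G>A", "c.6148-89G>A",
               "c.5460+1315_5460+1317delinsTA",
               "c.5460+1315_5460+1317delinsTA",
               "c.214+879_214+882delinsG", "c.214+879_214+882delinsG",
               "c.525+425_525+433delinsATA", "c.525+425_525+433delinsATA"),
    algorithm = c("SSFL", "HSF", "SSFL", "MaxEntScan", "SSFL", "HSF",
                  "SSFL", "NNSPLICE"),
    site_kind = "donor",
    wt_score = c(67.6, 70.2, 0, 0, 0, 61.2, 0, 0),
    mut_score = c(79.1, 82.5, 84.1, 7.9, 81.3, 74.0, 78.8, 0.91),
    scale_max = c(100, 100, 100, 12, 100, 100, 100, 1),
    stringsAsFactors = FALSE)

  # -- splice-assay band tables --------------------------------------------
  band <- function(gene, hgvs, construct, len, intensity, ignore = FALSE)
    data.frame(gene = gene, hgvs_c = hgvs, construct = construct,
               fragment_length_nt = len, intensity = intensity,
               ignore = ignore, stringsAsFactors = FALSE)
  assay_bands <- rbind(
    band("CDHR1", "c.783G>A", "wt", 500L, 100),
    band("CDHR1", "c.783G>A", "mut", 356L, 100),
    band("HGSNAT", "c.493+5G>A", "wt", 480L, 100),
    band("HGSNAT", "c.493+5G>A", "mut", 337L, 100),
    band("USH2A", "c.4758+3A>G", "wt", 225L, 100),
    band("USH2A", "c.4758+3A>G", "mut", c(332L, 225L), c(78.9, 21.1)),
    band("USH2A", "c.784+14389G>T", "wt", c(274L, 410L), c(96, 4),
         ignore = c(FALSE, TRUE)), # 410-nt artifact lane excluded
    band("USH2A", "c.784+14389G>T", "mut", c(371L, 274L), c(77.1, 22.9)),
    band("EYS", "c.5644+70912A>G", "wt", c(274L, 378L), c(76, 24)),
    band("EYS", "c.5644+70912A>G", "mut", 378L, 100),
    band("GRM6", "c.1355-587dup", "wt", c(492L, 359L), c(45.6, 54.4)),
    band("GRM6", "c.1355-587dup", "mut",
         c(492L, 359L, 567L, 610L), c(42.0, 37.0, 21.0, 6.5),
         ignore = c(FALSE, FALSE, FALSE, TRUE)), # heteroduplex lane
    band("ABCA4", "c.6148-89G>A", "wt", 410L, 100),
    band("ABCA4", "c.6148-89G>A", "mut", 410L, 100),
    band("ABCA4", "c.5460+1315_5460+1317delinsTA", "wt", 380L, 100),
    band("ABCA4", "c.5460+1315_5460+1317delinsTA", "mut", 380L, 100),
    band("CYP4V2", "c.214+879_214+882delinsG", "wt", 300L, 100),
    band("CYP4V2", "c.214+879_214+882delinsG", "mut", 300L, 100),
    band("PDE6B", "c.469-776C>G", "wt", 350L, 100),
    band("PDE6B", "c.469-776C>G", "mut", 350L, 100),
    band("RLBP1", "c.525+425_525+433delinsATA", "wt", 290L, 100),
    band("RLBP1", "c.525+425_525+433delinsATA", "mut", 290L, 100))

  assay_meta <- data.frame(
    gene = c("CDHR1", "HGSNAT", "USH2A", "USH2A", "EYS", "GRM6",
             "ABCA4", "ABCA4", "CYP4V2", "PDE6B", "RLBP1"),
    hgvs_c = c("c.783G>A", "c.493+5G>A", "c.4758+3A>G", "c.784+14389G>T",
               "c.5644+70912A>G", "c.1355-587dup",
               "c.6148-89G>A", "c.5460+1315_5460+1317delinsTA",
               "c.214+879_214+882delinsG", "c.469-776C>G",
               "c.525+425_525+433delinsATA"),
    wt_fragment_length = c(500L, 480L, 225L, 274L, 274L, 492L,
                           410L, 380L, 300L, 350L, 290L),
    event_kind = c("exon_skipping", "exon_skipping", "exon_elongation",
                   "pseudoexon_insertion", "pseudoexon_insertion",
                   "pseudoexon_insertion", NA, NA, NA, NA, NA),
    event_size = c(144L, 143L, 107L, 97L, 104L, 75L, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)

  # -- case table -----------------------------------------------------------
  all_ids <- c(named_ids, filler_ids)
  phen <- c(ph$named, setNames(ph$fill, filler_ids))
  wes_named <- c("Pt-4", "Pt-9", "Pt-11", "Pt-12", "Pt-14", "Pt-15",
                 "Pt-16", "Pt-17", "Pt-18", "Pt-21", "Pt-22", "Pt-52",
                 "Pt-61", "Pt-65")
  prior_method <- setNames(ifelse(all_ids %in% wes_named, "WES", "TCS"),
                           all_ids)
  prior_method[filler_ids[seq_len(40)]] <- "WES"
  prior_method[filler_ids[41:length(filler_ids)]] <- "TCS"
  cases <- data.frame(case_id = all_ids, phenotype = phen[all_ids],
                      prior_method = prior_method[all_ids],
                      stringsAsFactors = FALSE)
  cases <- cases[order(as.integer(sub("Pt-", "", cases$case_id))), ]

  ird_cohort(cases = cases, variants = variants, panel = panel,
             svs = svs, repeats = repeats,
             repeat_ranges = default_repeat_ranges(),
             assay_bands = assay_bands, assay_meta = assay_meta,
             alamut = alamut)
}

#' Write the fixture to a directory
#'
#' Emits the deterministic cohort as files ([write_cohort()]; variants as
#' VCF) together with the default configuration as `config.yaml`.
#'
#' @param dir output directory.
#' @param variant_format `"vcf"` (default) or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, variant_format = "vcf") {
  cohort <- build_cohort_fixture()
  write_cohort(cohort, dir, variant_format = variant_format)
  write_config(ird_config(), file.path(dir, "config.yaml"))
  invisible(dir)
}
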
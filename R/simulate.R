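#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the
#' study conditions: 100 probands, 24% with a resolvable (planted) causal
#' genotype, 56% monoallelic (one prior classified allele), the cohort
#' phenotype distribution, rare causal allele frequencies log-uniform on
#' 1e-6..5e-3 versus benign frequencies straddling the 1% gate,
#' well-separated in-silico scores for causal versus benign missense
#' draws, 20% coefficient of variation on assay band intensities, and a
#' plausible junction-microhomology profile.
#'
#' `score_separation` scales how far *every* causal evidence channel
#' stands out from background on a 0..1 axis: in-silico scores, SpliceAI
#' deltas, assay defect fraction, causal-allele rarity, SV exon overlap
#' and repeat expansion size all interpolate between a benign-like draw
#' (0) and a fully separated draw (1, the default).
#'
#' @param n_cases number of probands.
#' @param seed RNG seed (required for reproducibility).
#' @param causal_fraction fraction of cases receiving a planted causal
#'   genotype.
#' @param monoallelic_fraction fraction of cases carrying a prior
#'   classified first allele.
#' @param phenotype_probs named probability vector over
#'   [phenotype_levels()] (must sum to 1).
#' @param rare_af_bounds,benign_af_bounds log-uniform allele-frequency
#'   bounds for causal and benign draws.
#' @param score_separation causal-evidence separation in \[0, 1\].
#' @param assay_noise_cv coefficient of variation of band intensities.
#' @param microhomology_prob probability that a simulated SV junction
#'   carries microhomology; length drawn uniformly from
#'   `microhomology_range`.
#' @param microhomology_range integer length range of planted junction
#'   microhomology.
#' @param str_expansion_prob probability that a causal case is resolved
#'   by a repeat expansion rather than another mechanism.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 100L, seed = 1L,
                       causal_fraction = 0.24,
                       monoallelic_fraction = 0.56,
                       phenotype_probs = NULL,
                       rare_af_bounds = c(1e-6, 5e-3),
                       benign_af_bounds = c(5e-3, 5e-2),
                       score_separation = 1,
                       assay_noise_cv = 0.2,
                       microhomology_prob = 0.6,
                       microhomology_range = c(2L, 15L),
                       str_expansion_prob = 0.1) {
  if (is.null(phenotype_probs)) {
    counts <- c(53, 3, 3, 9, 1, 1, 2, 9, 1, 1, 1, 1, 1, 1, 7, 1, 1, 1, 1,
                1, 1)
    phenotype_probs <- setNames(counts / sum(counts), phenotype_levels())
  }
  if (abs(sum(phenotype_probs) - 1) > 1e-8)
    stop_field("phenotype probabilities must sum to 1")
  fr <- c(causal_fraction, monoallelic_fraction, score_separation,
          microhomology_prob, str_expansion_prob)
  if (any(fr < 0 | fr > 1)) stop_field("fractions must lie in [0, 1]")
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 causal_fraction = causal_fraction,
                 monoallelic_fraction = monoallelic_fraction,
                 phenotype_probs = phenotype_probs,
                 rare_af_bounds = rare_af_bounds,
                 benign_af_bounds = benign_af_bounds,
                 score_separation = score_separation,
                 assay_noise_cv = assay_noise_cv,
                 microhomology_prob = microhomology_prob,
                 microhomology_range = as.integer(microhomology_range),
                 str_expansion_prob = str_expansion_prob),
            class = "sim_config")
}

# log-uniform draw
rlunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# interpolate a causal evidence value toward its benign counterpart as
# separation decreases
sep_mix <- function(sep, benign, causal) (1 - sep) * benign + sep * causal

#' Generate a synthetic cohort with planted causal genotypes
#'
#' Builds an annotated-evidence cohort with the statistical structure the
#' analysis assumes. Each planted causal case receives one of five
#' genotype mechanisms — biallelic coding, coding plus deep-intronic with
#' a splice-assay defect, homozygous exon-deleting SV, dominant
#' whole-gene SV, or repeat expansion — with frequencies/scores from the
#' causal distributions; non-causal cases receive only benign-structured
#' evidence (common alleles, sub-threshold scores, deltas below 0.02).
#' Output is deterministic for a fixed seed. The planted truth labels are
#' returned separately and are never part of the cohort evidence.
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (an [ird_cohort()]) and `truth`
#'   (data.frame: case_id, causal, mechanism, gene).
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  panel <- default_panel()
  ranges <- default_repeat_ranges()
  sep <- cfg$score_separation
  n <- cfg$n_cases
  ids <- sprintf("S-%03d", seq_len(n))
  phen <- sample(names(cfg$phenotype_probs), n, replace = TRUE,
                 prob = cfg$phenotype_probs)
  method <- sample(c("WES", "TCS"), n, replace = TRUE, prob = c(0.54, 0.46))
  causal <- runif(n) < cfg$causal_fraction
  mono <- runif(n) < cfg$monoallelic_fraction
  ar_genes <- panel$gene[panel$inheritance == "AR" & panel$panel != "other"]
  ad_sv_gene <- "PRPF31"

  rare_af <- function(k = 1) {
    af <- rlunif(k, cfg$rare_af_bounds[1], cfg$rare_af_bounds[2])
    exp(sep_mix(sep, log(mean(cfg$benign_af_bounds)), log(af)))
  }
  benign_af <- function(k = 1) rlunif(k, cfg$benign_af_bounds[1],
                                      cfg$benign_af_bounds[2])
  # background loss-of-function alleles are common polymorphisms: they
  # must sit above the 1% gate (their rejection path is frequency)
  common_af <- function() runif(1, 0.0105, cfg$benign_af_bounds[2])
  causal_scores <- function() c(
    phylop = sep_mix(sep, runif(1, -2, 2), runif(1, 3, 6.2)),
    cadd = sep_mix(sep, runif(1, 1, 12), runif(1, 20, 40)),
    grantham = sep_mix(sep, runif(1, 0, 60), runif(1, 100, 205)))
  benign_scores <- function() c(phylop = runif(1, -2, 2),
                                cadd = runif(1, 1, 12),
                                grantham = runif(1, 0, 60))

  variants <- list(); svs <- list(); repeats <- list()
  bands <- list(); meta <- list(); truth <- list()
  vn <- 0L
  add_var <- function(case_id, gene, consequence, zygosity, af, scores,
                      deltas = c(NA, NA, NA, NA), prior = FALSE,
                      class = NA, event = NA) {
    vn <<- vn + 1L
    gi <- match(gene, panel$gene)
    variants[[length(variants) + 1L]] <<- data.frame(
      case_id = case_id, gene = gene, hgvs_c = sprintf("c.sim%d", vn),
      chrom = panel$chrom[gi],
      pos = panel$start[gi] + (vn * 97L) %% 50000L,
      ref = "A", alt = "G", consequence = consequence, zygosity = zygosity,
      af_gnomad = af, af_dbsnp = NA_real_, af_inhouse_eur = NA_real_,
      af_inhouse_asian = NA_real_,
      phylop = scores[["phylop"]] %||% NA_real_,
      cadd_phred = scores[["cadd"]] %||% NA_real_,
      grantham = scores[["grantham"]] %||% NA_real_,
      sai_ag = deltas[1], sai_al = deltas[2], sai_dg = deltas[3],
      sai_dl = deltas[4],
      prior_allele = prior, classification = class, hypomorphic = FALSE,
      predicted_event = event, stringsAsFactors = FALSE)
    sprintf("c.sim%d", vn)
  }
  no_scores <- list(phylop = NA_real_, cadd = NA_real_,
                    grantham = NA_real_)

  add_assay <- function(gene, hgvs) {
    # wild-type construct: single correctly spliced fragment; mutant:
    # pseudoexon band whose share scales with separation, plus noise
    wt_len <- 200L + (sum(utf8ToInt(hgvs)) %% 200L)
    ins <- 50L + (sum(utf8ToInt(hgvs)) %% 120L)
    defect_frac <- sep_mix(sep, 0, runif(1, 0.8, 1))
    noise <- function(x) pmax(x * (1 + rnorm(length(x),
                                             sd = cfg$assay_noise_cv)), 0)
    mut_int <- noise(c(100 * (1 - defect_frac), 100 * defect_frac))
    keep <- mut_int > 1e-6
    lens <- c(wt_len, wt_len + ins)[keep]
    ints <- mut_int[keep]
    if (!length(lens)) { lens <- wt_len; ints <- 100 }
    bands[[length(bands) + 1L]] <<- data.frame(
      gene = gene, hgvs_c = hgvs,
      construct = c("wt", rep("mut", length(lens))),
      fragment_length_nt = c(wt_len, lens),
      intensity = c(noise(100), ints), ignore = FALSE,
      stringsAsFactors = FALSE)
    meta[[length(meta) + 1L]] <<- data.frame(
      gene = gene, hgvs_c = hgvs, wt_fragment_length = wt_len,
      event_kind = "pseudoexon_insertion", event_size = ins,
      stringsAsFactors = FALSE)
  }

  random_flanks <- function() {
    rand_seq <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                         replace = TRUE), collapse = "")
    if (runif(1) < cfg$microhomology_prob) {
      k <- sample(seq(cfg$microhomology_range[1],
                      cfg$microhomology_range[2]), 1)
      mh <- rand_seq(k)
      list(left = paste0(rand_seq(max(25 - k, 5)), mh),
           right = paste0(mh, rand_seq(max(25 - k, 5))))
    } else {
      list(left = rand_seq(25), right = rand_seq(25))
    }
  }

  for (i in seq_len(n)) {
    id <- ids[i]
    mech <- NA_character_; causal_gene <- NA_character_
    if (causal[i]) {
      if (runif(1) < cfg$str_expansion_prob) {
        mech <- "repeat_expansion"
      } else if (mono[i]) {
        mech <- sample(c("coding_plus_intronic", "coding_plus_sv"), 1,
                       prob = c(0.8, 0.2))
      } else {
        mech <- sample(c("biallelic_coding", "hom_sv", "ad_sv"), 1,
                       prob = c(0.7, 0.15, 0.15))
      }
    }
    if (!is.na(mech) && mech == "repeat_expansion") {
      causal_gene <- "ATXN7"
      r <- ranges[ranges$locus == "ATXN7", ]
      exp_count <- round(sep_mix(sep, r$normal_max,
                                 runif(1, r$pathogenic_min + 5,
                                       r$pathogenic_min + 80)))
      repeats[[length(repeats) + 1L]] <- data.frame(
        case_id = id, locus = "ATXN7",
        allele1 = as.integer(exp_count),
        allele2 = sample(r$normal_min:r$normal_max, 1))
    } else if (!is.na(mech) && mech == "biallelic_coding") {
      causal_gene <- sample(ar_genes, 1)
      hom <- runif(1) < 0.3
      s1 <- causal_scores()
      if (hom) {
        add_var(id, causal_gene, "missense", "hom", rare_af(),
                as.list(s1))
      } else {
        lof_first <- runif(1) < 0.3
        if (lof_first) add_var(id, causal_gene, "nonsense", "het",
                               rare_af(), no_scores)
        else add_var(id, causal_gene, "missense", "het", rare_af(),
                     as.list(s1))
        add_var(id, causal_gene, "missense", "het", rare_af(),
                as.list(causal_scores()))
      }
    } else if (!is.na(mech) && mech == "coding_plus_intronic") {
      causal_gene <- sample(ar_genes, 1)
      add_var(id, causal_gene, "missense", "het", rare_af(),
              as.list(causal_scores()), prior = TRUE, class = "pathogenic")
      delta <- sep_mix(sep, runif(1, 0, 0.015), runif(1, 0.1, 0.9))
      hg <- add_var(id, causal_gene, "deep_intronic", "het", rare_af(),
                    no_scores, deltas = c(delta, 0, 0, 0),
                    event = "pseudoexon_insertion")
      add_assay(causal_gene, hg)
    } else if (!is.na(mech) && mech %in% c("coding_plus_sv", "hom_sv")) {
      causal_gene <- "RPGRIP1"
      gi <- match(causal_gene, panel$gene)
      ex <- panel$exons[[gi]][5, ] # the 101-bp exon
      nxt <- panel$exons[[gi]][6, ]
      # low separation pushes the deletion into the adjacent intron
      intron_mid <- (ex$end + nxt$start) %/% 2L
      center <- as.integer(round(sep_mix(sep, intron_mid,
                                         (ex$start + ex$end) %/% 2L)))
      half <- as.integer(round(sep_mix(sep, 30, runif(1, 800, 2500))))
      fl <- random_flanks()
      zyg <- if (mech == "hom_sv") "hom" else "het"
      svs[[length(svs) + 1L]] <- data.frame(
        case_id = id, chrom = panel$chrom[gi],
        start = center - half, end = center + half,
        svtype = "del", zygosity = zyg,
        left_flank = fl$left, right_flank = fl$right,
        stringsAsFactors = FALSE)
      if (mech == "coding_plus_sv")
        add_var(id, causal_gene, "frameshift", "het", rare_af(),
                no_scores, prior = TRUE, class = "pathogenic")
    } else if (!is.na(mech) && mech == "ad_sv") {
      causal_gene <- ad_sv_gene
      gi <- match(causal_gene, panel$gene)
      margin <- as.integer(round(sep_mix(sep, -2000, 500)))
      fl <- random_flanks()
      svs[[length(svs) + 1L]] <- data.frame(
        case_id = id, chrom = panel$chrom[gi],
        start = panel$start[gi] - margin, end = panel$end[gi] + margin,
        svtype = "del", zygosity = "het",
        left_flank = fl$left, right_flank = fl$right,
        stringsAsFactors = FALSE)
    } else {
      # non-causal background: one benign variant per rejection path
      g <- sample(ar_genes, 1)
      mode <- sample(3, 1)
      if (mono[i])
        add_var(id, g, "missense", "het", rlunif(1, 1e-5, 5e-3),
                list(phylop = runif(1, 3, 6), cadd = runif(1, 20, 40),
                     grantham = runif(1, 100, 200)),
                prior = TRUE, class = "pathogenic")
      if (mode == 1) add_var(id, g, "nonsense", "het", common_af(),
                             no_scores)
      else if (mode == 2) add_var(id, g, "missense", "het",
                                  rlunif(1, 1e-5, 5e-3),
                                  as.list(benign_scores()))
      else add_var(id, g, "deep_intronic", "het", rlunif(1, 1e-5, 5e-3),
                   no_scores, deltas = c(runif(1, 0, 0.015), 0, 0, 0))
    }
    truth[[i]] <- data.frame(case_id = id, causal = causal[i],
                             mechanism = mech, gene = causal_gene,
                             stringsAsFactors = FALSE)
  }

  bind <- function(x, cols) if (length(x)) do.call(rbind, x) else NULL
  cohort <- ird_cohort(
    cases = data.frame(case_id = ids, phenotype = phen,
                       prior_method = method, stringsAsFactors = FALSE),
    variants = do.call(rbind, variants),
    panel = panel,
    svs = bind(svs), repeats = bind(repeats),
    repeat_ranges = ranges,
    assay_bands = bind(bands), assay_meta = bind(meta))
  list(cohort = cohort, truth = do.call(rbind, truth))
}
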
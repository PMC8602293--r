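# Independent brute-force oracles and small builders used across tests.

# enumerate every subinterval and check the ROH definition directly;
# keep the maximal qualifying runs
roh_oracle <- function(pos, het, cfg = triage_config()) {
  n <- length(pos)
  w <- cfg$roh_min_snps
  if (n >= w) {
    cs <- c(0L, cumsum(as.integer(het)))
    nwin <- n - w + 1L
    win_het <- cs[(w + 1L):(n + 1L)] - cs[1:nwin]
  }
  qualifies <- function(i, j) {
    if (j - i + 1L < w) return(FALSE)
    if ((pos[j] - pos[i]) / 1000 < cfg$roh_min_kb) return(FALSE)
    all(win_het[i:(j - w + 1L)] <= cfg$roh_window_het)
  }
  runs <- list()
  for (i in seq_len(n)) for (j in i:n)
    if (qualifies(i, j)) runs[[length(runs) + 1L]] <- c(i, j)
  if (!length(runs)) return(data.frame(start_index = integer(),
                                       end_index = integer()))
  keep <- vapply(runs, function(r) {
    !any(vapply(runs, function(s)
      s[1] <= r[1] && s[2] >= r[2] && !(s[1] == r[1] && s[2] == r[2]),
      logical(1)))
  }, logical(1))
  m <- do.call(rbind, runs[keep])
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start_index = m[, 1], end_index = m[, 2])
}

# exhaustive maximum shared suffix/prefix length
microhomology_oracle <- function(left, right) {
  best <- 0L
  for (k in seq_len(min(nchar(left), nchar(right)))) {
    suf <- substr(left, nchar(left) - k + 1L, nchar(left))
    pre <- substr(right, 1L, k)
    if (identical(suf, pre) && !grepl("N", suf, fixed = TRUE)) best <- k
  }
  best
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# minimal two-gene panel for unit tests
tiny_panel <- function() {
  validate_panel(data.frame(
    gene = c("GENE1", "GENE2"),
    chrom = c("chr1", "chr2"),
    start = c(1000L, 5000L), end = c(20999L, 25999L),
    panel = "ird", inheritance = c("AR", "AD_incomplete_penetrance"),
    promoter_start = c(400L, 4400L), promoter_end = c(999L, 4999L),
    exons = I(list(
      data.frame(start = c(2000L, 6000L, 10000L),
                 end = c(2100L, 6103L, 10100L)),
      data.frame(start = c(7000L, 9000L), end = c(7100L, 9100L))))))
}

tiny_case <- function(case_id = "T-1",
                      phenotype = "Retinitis pigmentosa") {
  data.frame(case_id = case_id, phenotype = phenotype,
             prior_method = "WES", stringsAsFactors = FALSE)
}

tiny_variant <- function(case_id = "T-1", gene = "GENE1",
                         hgvs = "c.100A>T", consequence = "nonsense",
                         zygosity = "het", af_gnomad = 1e-4, ...) {
  validate_variants(data.frame(
    case_id = case_id, gene = gene, hgvs_c = hgvs, chrom = "chr1",
    pos = 1500L, ref = "A", alt = "T", consequence = consequence,
    zygosity = zygosity, af_gnomad = af_gnomad, ...,
    stringsAsFactors = FALSE))
}
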
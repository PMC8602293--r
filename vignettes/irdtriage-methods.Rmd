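---
title: "Methods: variant prioritization and case resolution for IRD cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritization and case resolution for IRD cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdtriage)
```

## Scope and model of the analysis

`irdtriage` implements the interpretation half of a whole-genome
sequencing (WGS) diagnostic workflow for inherited retinal disease
(IRD) probands unresolved after panel or exome sequencing. Everything
upstream — alignment, variant/SV/STR calling, VEP-style annotation, and
the splice-prediction algorithms themselves — is out of scope: the
package *consumes* annotated records (population frequencies,
PhyloP/CADD/Grantham, SpliceAI deltas, Alamut-style score pairs) and
*produces* per-case diagnostic decisions. The unit of analysis is the
proband; the decision space is {solved, likely_solved, unsolved}.

The pipeline is a composition of deterministic decision rules rather
than a fitted statistical model, which is why the package exposes
per-stage functions plus an orchestrator (`run_cohort()`) instead of a
single `fit()`-style interface.

## Stages and their parameters

### Frequency gating (`frequency_pass()`)

A variant stays causative only while every *annotated* source frequency
is at or below its gate: gnomAD 1%, dbSNP 5%, in-house European 1%,
in-house Asian 2% (all config-overridable, `triage_config()`). The
gnomAD gate is the binding WGS-stage rule; the other gates describe the
prior screening stage and bind only when those sources are present on a
record. A missing source never fails the gate — novel indels unreported
in gnomAD must survive gating. Rare-intronic interrogation of a gene of
interest uses the same 1% ceiling (`intronic_max`).

### The missense two-of-three rule (`missense_causative()`)

Thresholds are PhyloP ≥ 2.7 (documented input range −14.1..6.4),
CADD-PHRED ≥ 15 (range 1..99) and Grantham ≥ 80 (range 0..215), all
inclusive, matching the "predicted pathogenic ≥" phrasing of the
protocol. A variant passing only one threshold is excluded;
`min_passed_scores` defaults to 2. All three scores absent is an error
(the variant is uninterpretable), never a silent pass.

### Effect ordering and the two-branch protocol (`prioritize_case()`)

Small variants rank nonsense < frameshift < canonical splice < NCSS <
in-frame indel < missense < synonymous; deep-intronic, UTR and other
classes rank after synonymous. For monoallelic cases (any record with
`prior_allele` set), SVs hitting the prior gene are evaluated first,
then rare intronic variants of that gene, then the genome-wide branch;
without a prior allele, SVs rank before effect-ordered SNVs, and once a
top candidate is held its gene enters rare-intronic interrogation.
Repeat expansions are screened for every case. Ties are broken by
(gene, chromosome, position), making prioritization invariant to input
order — the protocol itself does not specify a tie order, so we chose
the simplest deterministic one.

### ROH scanning (`roh_scan()`)

The plink-style parameters are window-het = 3, snp = 50, kb = 300. The
published protocol names the parameters but not plink's full run
extension heuristics, so the package implements the directly testable
windowed reading: a reported run is a maximal stretch of ≥ 50 sites
spanning ≥ 300 kb in which *every* window of 50 consecutive sites has
≤ 3 heterozygous calls. This contract is verified against a brute-force
enumeration of all qualifying subintervals in the tests. ROH output is
advisory only (it can flag genes for homozygous-candidate review); no
gate consumes it, because the protocol states no decision rule tied to
ROH.

### Splice-assay candidacy (`select_splice_candidates()`)

A frequency-passed NCSS or deep-intronic variant is selected when any
of its four SpliceAI deltas (acceptor/donor gain/loss) reaches 0.02.
The comparison is implemented inclusive (≥) with a strict (>) toggle:
no worked example pins the exact-boundary behaviour, so the choice is
exposed rather than hidden. The 500-bp SpliceAI context is metadata
(scores are inputs). For indels SpliceAI cannot score, the delta block
is absent and candidacy falls back to the Alamut route: at least two
algorithms (SSFL, MaxEntScan, GeneSplicer, HSF, NNSPLICE) showing a
gained or strengthened site, where "strengthened" means a score
increase of at least 5% of that algorithm's scale maximum and "gained"
means a positive mutant score from a zero/absent wild-type score. The
original criteria are cited to earlier work and not restated in the
protocol; the ≥ 2-algorithm, ≥ 5%-of-scale rule is this package's
concrete, config-overridable default, chosen so that every enumerated
candidate of the study fixture selects and no filler variant does. The
two signals are OR-combined (a variant with deltas present but below
threshold is *not* rescued by Alamut; the `alamut_only` trigger is
reserved for absent delta blocks, matching the indel narrative).

### Splice-assay interpretation (`interpret_assay()`)

Band tables carry per-lane fragment length, gel intensity (arbitrary
units) and an `ignore` flag for heteroduplex/artifact lanes, which the
band-table author excludes from quantification (as the study did).
Percentages are intensity shares of the non-ignored lanes of a
construct, so the result is invariant to rescaling a lane profile.

A splice defect is called when the mutant construct shows a fragment
absent from the wild-type construct above 5% of lane intensity, **or**
when the wild-type fragment's share drops more than 10 percentage
points below its share in the wild-type construct. The second clause
is required by constructs whose wild-type assay already shows the
aberrant band (e.g. a minigene with a baseline 24% pseudoexon band
whose mutant loses all full-length product): a novel-fragment-only rule
would miss a complete loss of wild-type product.

Severity uses the protocol's single published cut — < 25% remaining
wild-type product is severe — extended to a total function with a mild
boundary at ≥ 75% (the label given to a 91% allele) and moderate in
between; both boundaries are `assay_config()` parameters. Severity is
classified on the *normalized* percentage: the mutant construct's
wild-type share divided by the wild-type construct's, capped at 100.
Percentages are rounded to the nearest integer before the ratio and
the ratio is rounded to the nearest integer, reported at one decimal —
the only convention consistent with the published 42/46 × 100 = 91.0.
The "moderately severe" label of two known deep-intronic alleles is a
genotype–phenotype fixture annotation, never computed from band
intensities.

Expected fragment lengths follow the event arithmetic: insertions
(pseudoexon insertion, exon elongation) add the event size to the
wild-type fragment; skipping and partial exon deletion subtract it,
with size < wild-type length enforced. One fixture assay records a
partial-exon-deletion lane whose printed length does not reconcile with
this arithmetic; lane lengths are treated as data for that assay and
the reconciling pseudoexon event is the one the fixture models.

### SV and repeat interpretation

`sv_length()` is `end − start + 1` on 1-based inclusive coordinates
(the convention that reconciles the published 26.68-kb deletion with
its printed breakpoints); on-disk BED panels are 0-based half-open and
converted losslessly. `genes_disrupted()` classifies each overlapped
panel gene as whole-gene, multi-/single-exon (by exons overlapped),
promoter-only, or intronic-only. The reading-frame effect of an exonic
deletion is the summed deleted coding length mod 3 where exon intervals
are available, `unknown` otherwise — the protocol reports frame
outcomes but not its computation. `microhomology()` returns the longest
k-suffix of the retained left context equal to the k-prefix at the
right junction; `N` never matches; repetitive-element family annotation
is out of scope. `classify_repeat()` partitions counts into normal /
indeterminate / pathogenic by the locus range table (ATXN7: 3–19
wild-type, 37–460 pathogenic; the gap 20–36 and counts beyond the
documented maximum are indeterminate).

### Case resolution (`resolve_case()`)

An allele fully qualifies when it is (a) a frequency-passed
loss-of-function coding variant (nonsense, frameshift, canonical
splice), (b) classified pathogenic or likely pathogenic, (c) a marked
hypomorphic allele (these qualify despite frequency or score softness —
the workflow treats them as causative in specific genotypes), (d) an
NCSS/deep-intronic variant whose assay shows a defect (severe,
moderate or mild), (e) an *unclassified* missense passing all three
in-silico thresholds, or (f) a gene-disrupting SV. A pathogenic repeat
expansion qualifies at its locus. A VUS passing all three thresholds
carries partial weight only.

Recessive genes solve with total qualifying weight ≥ 2 (homozygous
counts twice); dominant and dominant-incomplete-penetrance genes solve
with a single loss-of-function SV or repeat expansion. One fully
qualifying allele plus an all-thresholds VUS yields likely-solved —
the strictest reading that reproduces the study's one likely-solved
case, whose VUS was kept on the strength of unanimous predictions.
Rule (e) is the package's resolution of a gap: newly identified second
missense alleles in the study were classified by its authors before
counting, but a synthetic cohort has no author in the loop; requiring
unanimity (3/3, stricter than candidacy's 2/3) for unclassified
missense keeps the generator's planted alleles recoverable without
letting weak background missense resolve cases. Assay-no-defect
partners never qualify, leaving their cases unsolved with the evidence
retained in the report (candidates excluded by gates stay in the
evidence chain for auditability).

## The synthetic cohort generator

`generate_cohort()` emulates the evidence structure the rules assume:
100 probands by default, 24% carrying a planted causal genotype, 56%
monoallelic, phenotypes drawn from the cohort's published distribution,
causal allele frequencies log-uniform on 1e-6..5e-3 against benign
frequencies straddling the 1% gate, causal in-silico scores drawn above
all three thresholds against benign scores below them, assay band
intensities with 20% coefficient of variation, junction microhomology
planted on 60% of simulated SVs (2–15 bp), and a repeat-expansion
mechanism for 10% of causal cases. Planted mechanisms cover the five
resolution routes: biallelic coding, coding + deep-intronic with an
assay defect, homozygous exon-deleting SV, dominant whole-gene SV, and
repeat expansion. Truth labels are emitted separately and never read by
the pipeline.

`score_separation` scales every causal evidence channel between a
benign-like draw (0) and full separation (1, the default): scores,
deltas, assay defect fraction, causal-allele rarity, SV exon overlap
and repeat size. Both limits are verified: at separation 1 the solved
set equals the planted causal set exactly; at 0 nothing resolves.
Background (non-causal) evidence is constructed to fail exactly one
gate — frequency, score count, or delta threshold — which exercises
every rejection path and makes false-positive resolutions structurally
impossible rather than merely improbable.

What the generator does **not** emulate: linkage between variants and
real transcript structure, annotation errors, caller false positives,
population stratification in frequencies, retina-specific splicing
(assay outcomes in HEK293-like systems are taken at face value), and
X-linked screening. Passing tests on synthetic cohorts therefore show
that the decision logic is implemented correctly under the stated
evidence model, not that the thresholds themselves are clinically
optimal.

## The deterministic fixture

`build_cohort_fixture()` encodes, as raw evidence only, the 24 published
solved-case genotypes, the 14 splice-candidate individuals with their
score triggers, the 11 assay band tables (6 with defects, 5 without),
both structural variants with their breakpoints, the ATXN7 expansion
(70 repeats), the hypomorphic-allele annotations, and 69 filler cases
that match the published phenotype histogram and each fail exactly one
gate. Status labels are absent from the inputs; resolution must
recompute them. Gene coordinates are a miniature self-consistent
annotation — only the chromosome-19 deletion region uses the published
breakpoints, because the deletion size is the only printed quantity
that depends on real coordinates. One published proband identifier is
inconsistent between the study's table and text (and one allele label
differs by a digit); the fixture follows the table throughout.

## Numerical choices and degenerate inputs

* Rounding uses R's `round()` (IEEE round-half-even); the normalization
  convention (integers before the ratio, integer ratio, one-decimal
  report) is fixed by the published 91.0 and applied uniformly.
* All-zero lane intensities, empty Alamut pair lists, all-absent
  missense scores, unknown repeat loci and unsorted genotype tracks are
  errors, not defaults.
* Readers never impute numeric values for missing annotations; absent
  fields stay `NA` end-to-end.
* VCF INFO values percent-encode the characters reserved by the format
  (`;`, `=`, `,`, `%`, space), so compound HGVS labels survive a
  VCF round trip byte-for-byte.
* Problem sizes in the test suite — 200-case synthetic cohorts for
  recall, ≤ 200-site ROH tracks and ≤ 30-nt flanks against brute-force
  oracles — were chosen as the smallest sizes at which every rule and
  boundary is exercised, and keep the full suite in the low minutes on
  one core.

## Known limitations

Phase is assumed in trans for compound heterozygotes unless stated;
digenic models, penetrance modelling, the full ACMG-AMP evidence-code
engine, HGVS parsing (c. strings are opaque labels; all computation
uses explicit genomic fields) and X-linked logic are out of scope. The
Alamut candidacy rule is a concrete stand-in for criteria the protocol
cites but does not restate, and the moderate severity band (25–75%) has
no published anchor other than the two labels it must be consistent
with; both are configuration, not constants.
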
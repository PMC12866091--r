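---
title: "Methods: germline and somatic mutational landscapes in blood/normal/tumor triplets"
author: "tripletmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline and somatic mutational landscapes in blood/normal/tumor triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletmut)
```

# The analytical model

`tripletmut` analyses whole-exome variant calls from *triplets*: matched
peripheral blood (B), cancer-adjacent normal tissue (A) and tumor (T)
samples of the same patient. Blood serves as the germline reference, so the
presence pattern of a variant across the three tissues determines its
origin:

* **germline**: detected in all three tissues (B∩A∩T);
* **somatic**: detected in tumor and/or adjacent normal but absent from
  blood — subdivided into *shared somatic* (A∩T), *tumor-private* (T only)
  and *normal-private* (A only);
* the remaining presence patterns (B∩A, B∩T, B only) arise only through
  detection dropout and are retained as explicit classes rather than
  silently merged.

The seven classes partition every patient's variant set; the class is a
pure function of the three presence bits. Matching between tissues is
allele-exact at the variant level (canonical keys with shared-base
trimming) and symbol-based at the gene level; overlap figures (Venn
regions, Jaccard indices) default to the gene level while VAF analyses are
always allele-exact.

Shared somatic variants are the molecular signal of *field cancerization*:
clones carrying cancer-associated mutations that expanded in histologically
normal tissue before (or independently of) the tumor. Two quantities
summarise their clonal structure: the variant allele frequency (VAF,
alt-supporting reads over depth) distribution of somatic variants in the
normal tissue, and the per-variant tumor-to-normal VAF ratio, whose
concentration around 1 indicates comparable clonal representation in both
tissues.

# Filtering

Variants enter the analysis only after three conjunctive filters, applied
in a fixed order with each rejected record attributed to exactly one rule:

1. **Quality hard filters** (GATK-style site and genotype metrics). SNVs
   fail on `DP < 4`, `QD < 2`, `FS > 60`, `MQ < 35`, `MQRankSum < -12.5`,
   `ReadPosRankSum < -8`; indels on `DP < 4`, `QD < 2`, `FS > 200`,
   `MQ < 35`, `ReadPosRankSum < -20`; genotypes on `GQ < 20`. The
   inequalities are strict exactly as written, so boundary values pass. A
   record missing a QC metric skips that rule instead of failing — failing
   on missingness would discard entire annotation-poor cohorts.
2. **Exonic non-silent**: nonsynonymous, stop gain/loss, frameshift and
   non-frameshift indels; splicing is counted as non-silent by default
   (conventional for exome impact analyses) and is configurable.
   Synonymous, intronic and UTR records are removed.
3. **High functional impact (HFI)**: predicted deleterious by the MetaSVM
   ensemble (`D`) *or* classified pathogenic by ClinVar. The disjunction is
   deliberate; missing annotations never qualify. "Likely pathogenic" is
   included in the qualifying ClinVar set by default and can be switched
   off.

Filter reports are additive: input count = output count + the sum of
per-rule exclusive drops, and tightening any threshold can only shrink the
output.

# Statistical procedures

**Differential mutation.** Per gene, patients are cross-tabulated as
mutated/non-mutated in two tissues and tested with the two-sided Fisher
exact test, computed by hypergeometric enumeration under the conventional
"minlike" rule (sum over all tables with point probability not exceeding
the observed one, relative tolerance `1e-7`, matching `stats::fisher.test`).
Multiplicity is controlled by Benjamini–Hochberg step-up q-values, and the
effect size is Cramér's V (`sqrt(chi^2/n)`, uncorrected chi-square; for a
2×2 table this is the magnitude of the phi coefficient). Odds ratios use
the sample cells; the Haldane–Anscombe +0.5 correction is applied to all
four cells *only* when a cell is zero and *only* for the log-OR used in
ranking and display — the exact p-value is never modified, keeping the test
exact and the ranking finite.

**Mutation burden** is variants per megabase of gene model, correlated
with age by Pearson's r (two-sided t-test); zero-variance inputs yield an
explicit "undefined" result rather than NaN.

**Preranked GSEA.** Genes are ranked by the log odds ratio of mutation
frequency between two tissues (reference tissue in the denominator),
descending with alphabetical tie order. The enrichment score is the
classic weighted Kolmogorov–Smirnov running sum: hit increments
`|score|^p` normalised over in-set genes (`p = 1` by default), miss
decrements `1/(N - n_set)`, ES the maximum deviation. Significance comes
from gene-label permutations (default 1000, seeded): the NES divides ES by
the mean of same-sign permutation scores and the p-value is the same-sign
tail fraction with +1 smoothing; FDR q-values are BH across gene sets.
These defaults (permutation count, weighting) are this package's choices —
standard preranked-GSEA practice — and are exposed as configuration.

**Pathway attribution.** Gene-level hits are mapped into pathway catalogs
(GMT input: MSigDB Hallmark, KEGG, or any curated collection). Patient ×
pathway alteration matrices mark pathways with at least one qualifying
member-gene hit. The germline-versus-somatic contribution of a pathway is
the per-patient percentage of member genes altered by each origin group,
averaged over patients, under two definitions: **A** — somatic =
tumor-private, germline = shared by all three tissues; **B** — somatic =
normal-private plus normal∩tumor-shared, germline = all-shared plus
blood∩normal-shared. Under definition A the origin classes are disjoint
per gene, so the two percentages sum to at most 100. A gene hit by both a
germline and a somatic variant in the same patient counts once in each
origin category (the percentages are per-origin). Pathways with no member
gene in the cohort's annotation universe are flagged and excluded from
averages.

**Mutational signatures.** SNVs are mapped to the 96 pyrimidine-centred
trinucleotide channels (purine-centred records are projected through the
reverse complement, making the spectrum strand-invariant), in the COSMIC
file row order so catalogs load without remapping. Decomposition onto a
known catalog is by per-sample nonnegative least squares, with exposures
normalised to fractions and the observed/reconstructed cosine similarity
reported. Attributed mutation counts use largest-remainder rounding so
per-sample counts sum exactly to the SNV total. A fixed-rank de novo NMF
(Frobenius multiplicative updates, seeded restarts) is provided for
exploration; model selection across ranks, and stability analysis of the
SigProfiler kind, are out of scope. NMF factorisations are only
identifiable when signature supports are sufficiently separable — the
tests therefore assert recovery on disjoint-support mixtures and treat
overlapping-support cases as refitting (NNLS) problems. Cohort-level
spectrum differences are tested with the Wilcoxon signed-rank test (exact
null for n ≤ 25 without ties, normal approximation with tie and continuity
correction otherwise; zero differences dropped first).

# The synthetic cohort generator

Patient-level data from the cohorts this design mirrors are access
controlled, so every stage is validated against a generator that emulates
the study conditions and records full ground truth (origin class, true
per-tissue VAF, generating signature and channel for every variant).

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| patients | 24 | size of the discovery cohort design |
| coverage B/A/T | 100×/100×/200× | stated sequencing depths |
| depth model | Poisson(mean) | standard one-parameter WES shorthand; a fixed-depth mode exists for detection-limit diagnostics |
| detection rule | ≥ 10 alt reads | the study's supporting-read requirement; implies minimal detectable VAFs of 0.10 (100×) and 0.05 (200×) |
| germline VAFs | 0.5 / 1.0 at 85/15 | typical exome het/hom ratio; the study reports no value, so this is a knob, not a claim |
| somatic VAFs | Beta, median 0.216, IQR 0.117 | re-parameterised by the reported normal-tissue somatic VAF summary; the quantile inversion solves for the Beta shapes numerically |
| class counts per patient | 150 germline, 15 shared-somatic, 25 tumor-private, 10 normal-private | a dominant shared-germline fraction with realistic somatic minority; chosen once as plausible HFI-scale counts |
| signature mixture | 0.19/0.59/0.22 over three synthetic signatures | echoes the reported per-signature contribution structure |
| HFI pass fraction | 0.5 | keeps both retained and rejected annotation strata populated at desk scale |
| ages | uniform 23–49 | the study's age range |

Substitutions are drawn channel-first from the signature mixture and then
placed at genomic positions whose trinucleotide context matches the
channel on either strand, so simulated spectra are exact multinomial draws
from the mixture and context-aware by construction. Annotations (MetaSVM,
ClinVar, functional class) are constant across a patient's tissues, which
guarantees that the impact filter removes a variant consistently in all
tissues and never distorts origin classes. Read support is drawn
independently per tissue; a variant is emitted only where it reaches the
supporting-read threshold, which reproduces the real detection asymmetry:
low-VAF somatic variants drop out of the 100× tissues far more often than
germline heterozygotes, whose VAF sits well above every detection limit.

A single global seed fans out to per-patient streams through a fixed
multiplicative hash, so cohorts are reproducible and patients independent;
re-running any configuration byte-identically reproduces all outputs.

What the generator does *not* emulate — and hence what green tests do not
show about real data: sequencing error and alignment artifacts (all emitted
read support comes from the true allele), mutational hotspots and
gene-length biases (positions are uniform within context pools), sample
purity and copy-number distortion of VAFs, inter-patient sharing of
germline polymorphisms, and annotation errors. The recovery results
should be read as *software correctness* under the stated read-sampling
model, not as evidence about biological detectability.

# Numerical choices and degenerate inputs

* Quantiles (median, IQR) use type-7 linear interpolation throughout.
* Jaccard of two empty sets is defined as 0.
* A shared-somatic variant with zero normal-tissue VAF is excluded from
  the ratio analysis and counted in a diagnostics field.
* Zero-depth loci in the binomial presence re-validation are "no-call",
  never "absent"; the test is the exact one-sided binomial tail against a
  per-read error rate (default 0.01). This simple coverage-aware check
  stands where a published multi-class recalling procedure is not
  reproducible from its description.
* Signature catalogs must have exactly 96 rows, nonnegative entries and
  column sums within `1e-3` of 1 (then renormalised exactly); anything
  else is rejected rather than repaired.
* All-zero spectra refit to zero exposures with an undefined-similarity
  flag. NMF restarts are seeded and the best Frobenius fit is kept, so a
  fixed seed gives bit-identical factors.
* Ties in gene rankings are broken alphabetically; ties in
  largest-remainder rounding by index — every ordering in the package is
  deterministic.

# Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
cohorts of 4–24 patients over 120–500 simulated genes (roughly 200–5,000
variants per cohort), with 10,000-mutation spectra for signature-recovery
checks, 1,000 gene-label permutations for GSEA calibration and a full
enumeration sweep of 2×2 tables with per-arm margins up to 30. These sizes
were chosen so that the entire validation suite runs in a few minutes on a
single CPU while keeping every statistical check adequately powered.

# Known limitations

* The pipeline starts from annotated VCFs; alignment, raw calling and
  annotation (BWA/GATK/ANNOVAR equivalents) are upstream and out of scope.
* Phylogenetic reconstruction of clonal order and any expression-level
  integration are out of scope.
* Gene-level "shared" calls inherit annotation granularity: two different
  variants in the same gene count as a shared gene alteration.
* The de novo NMF is a fixed-rank exploratory tool; do not interpret its
  factors as validated signatures without refitting against a curated
  catalog.
* The bundled signature catalog is synthetic (see
  `demo_signature_catalog()`): shaped after the clock-like/flat/
  artifact-like trio for realistic testing, but not the COSMIC reference
  values, which users should supply as a TSV for real analyses.
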
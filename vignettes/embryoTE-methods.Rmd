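---
title: "embryoTE: models, parameters and design choices"
author: "embryoTE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{embryoTE: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoTE)
```

# Scope

embryoTE implements the computational core of a single-embryo and bulk
RNA-seq study of mouse models carrying hypomorphic alleles of an X-linked
glycosyltransferase: repeat-aware retrotransposon quantification,
in-silico sexing/genotyping/QC of single-embryo libraries, a
negative-binomial Wald differential-expression (DE) engine with
unwanted-variation covariates, and the enrichment and
developmental-delay statistics used downstream. Alignment, trimming and
transcript quantification are out of scope: the package consumes
alignments (SAM) and count matrices. All stages are exercised on a
seeded synthetic-data generator, so the full chain is testable without
external downloads.

# Retrotransposon quantification

Multi-mapping reads make per-insertion quantification unreliable when an
aligner reports a single random best alignment, so quantification is
aggregated at the repName level of a three-tier RepeatMasker-style
catalog (repName within repFamily within repClass). The stage applies:

1. **Annotation loading** (`loadRepeatAnnotation`): RepeatMasker `.out`
   dialect or extended BED; `Simple_repeat` and `Low_complexity` classes
   are excluded by default, matching the analysis convention for
   transposon-derived transcripts.
2. **Fragment filter** (`filterRepeatFragments`): a paired-end fragment
   is kept iff *both* mates are fully contained each within a single
   repeat element and *neither* mate overlaps a gene body by at least
   1 bp (unstranded). Containment against a *single* element is
   deliberate: a mate spanning two abutting copies of the same repName
   is not contained, mirroring full-overlap fragment counting.
3. **Counting** (`countByRepName`): the unit is the fragment; a fragment
   counts for repName R iff both mates lie in elements of repName R.
   Pairs whose mates fall in elements of different repNames are
   discarded as ambiguous and reported. The catalog does not state how
   such pairs should be treated; discarding follows the default
   ambiguity handling of fragment-counting tools and is our documented
   choice.
4. **FPKM** (`fpkmByRepName`, `fpkmByRepFamily`): with `inputReads` the
   aligner *input read* count for the sample,

   FPKM(r, s) = count(r, s) / (inputReads(s)/2) × 10⁶ / lengthKb(r),

   where the division by two converts reads to fragments, and
   lengthKb(r) is the summed length of all elements of the repName. The
   family-level value aggregates member *counts* and member *lengths*
   (never the mean of member FPKMs).
5. **DNA-contamination covariate** (`dnaContamination`): genomic-DNA
   carry-over shows up as expression of DNA transposons, which have no
   appreciable transcriptional activity in this system. The per-sample
   sum of DNA-class FPKM enters the repeat DE design as a covariate
   (`~ dnaFpkm + condition`); samples whose value exceeds
   median + 3×MAD are flagged. The original check was visual; the
   median/MAD rule is our reproducible stand-in and its multiplier is
   configurable.

# Single-embryo QC, sexing and genotyping

* **QC** (`qcFilterEmbryos`): embryos with fewer than 10⁶ reads are
  discarded; among the remainder, per-axis robust outliers
  (|x − median| > 3×MAD on mitochondrial fraction or rDNA fraction) are
  removed. The outlier rule replaces a visual scatter-plot inspection;
  a zero MAD means no outliers on that axis, and with fewer than four
  depth-passing embryos the outlier step is skipped with a warning.
* **Sexing** (`assignSex`): the summed size-factor-normalized counts of
  the Y-linked genes (Ddx3y, Eif2s3y) score each embryo; male iff the
  score exceeds the threshold (default 10 normalized counts — the
  original assignment had no printed cutoff; ours is conservative,
  configurable, and reported together with a bimodality diagnostic and
  an optional ambiguity band).
* **Tag genotyping** (`genotypeFromTagCounts`): wild type iff the sum of
  degron-tag-mapping reads is strictly below 72, the printed decision
  boundary; a step function with a single transition.
* **Allele calling** (`callAlleleAtLocus`): reads over the mutated codon
  are classified by exact substring consistency against WT, missense and
  deletion templates. The 3-bp deletion allele is recognized from reads
  whose aligned prefix matches WT up to the codon and whose soft-clipped
  tail matches the post-deletion junction — the caller never relies on
  deletion-aware alignment records, because an end-to-end aligner
  represents such reads as match + soft-clip. Calls require `minReads`
  (default 3) informative reads; two alleles each with `minReads` and at
  least `hetMinFraction` (default 0.2) of informative reads give a
  heterozygous call. A WT call with zero mutant reads carries a
  `wtByAbsence` qualifier, since absence of mutant reads cannot formally
  exclude a heterozygous embryo.

# The negative-binomial DE engine

`nbWaldTest` fits, per feature, a log-link NB GLM with median-of-ratios
size factors as offsets and an arbitrary design (condition plus
covariates such as the DNA FPKM or unwanted-variation factors W1…Wk).

* **Dispersion**: per-feature Cox–Reid adjusted profile maximum
  likelihood at the Poisson-fit means, then maximum a-posteriori
  moderation under a log-normal prior centred on a fitted
  mean–dispersion trend (α(μ) = a₀ + a₁/μ, robustly fitted); the prior
  variance is estimated from the spread of gene-wise estimates around
  the trend with a floor of 0.25. This is an approximation to the
  published moderated estimator; small numerical discrepancies from
  that tool are expected and out of contract.
* **Test**: Wald statistic on the condition coefficient; two-sided
  p-values use a *t* reference with residual degrees of freedom rather
  than the normal, because at single-embryo group sizes the normal
  reference is visibly anticonservative in the far tail (we measured a
  ~5-fold excess below 10⁻⁴ at n = 5 + 5); the t reference restores
  validity at the cost of mild conservatism. Fold changes are
  unshrunken MLEs (display-side shrinkage is out of scope).
* **Multiplicity**: step-up Benjamini–Hochberg over non-NA p-values;
  features failing to converge are reported NA and excluded from the
  denominator.
* **Independent filtering** (`independentFiltering`): baseMean-quantile
  thresholds from 0 to 95% in 1% steps; the threshold maximizing
  rejections at the optimization cutoff (default 0.05) is chosen, ties
  toward the lowest threshold; filtered features get padj = NA.
* **Control genes and RUV** (`selectControlGenes`, `ruvFactors`):
  controls must satisfy, in every provided contrast, baseMean > 100,
  padj > 0.8 and |log2FC| < 0.05. The fold-change criterion is stated
  as "log2FC < 0.05" in the source convention; we read it as an
  absolute value, since a signed reading would admit strongly
  downregulated genes and defeat the purpose — a `signed` flag restores
  the literal reading. Factors of unwanted variation are the first k
  (default 6) left-singular coordinates of the samples from the
  per-gene-centred log(normalized count + 1) matrix of control genes,
  sign-fixed so each column's largest-magnitude entry is positive.
* **PCA** (`pcaEmbed`): log2(normalized counts + 1), drop features with
  mean normalized count ≤ 10, keep the top 1000 by variance, centred
  unscaled PCA; variance-explained fractions are reported.
* **TPM** (`computeTPM`): length-first normalization; every sample
  column sums to 10⁶.

The pseudocount in the PCA/RUV transforms is log(x + 1) (unspecified in
the source; documented here once).

# Enrichment and secondary statistics

* **Ranking** (`rankBySignedSignificance`): score =
  −log10(padj)·sign(log2FC), padj floored at 10⁻³⁰⁰ to keep scores
  finite; ties break by |log2FC| (more extreme first) then feature id.
* **GSEA** (`runGSEA`): weighted running sum (hit increments
  |score|^weight normalized, miss decrements 1/(N−Nh)); ES is the signed
  maximum deviation. The null is gene-label permutation (sample-level
  permutation is impossible at the summary level the rank list
  carries); NES divides ES by the mean |null ES| of matching sign, and
  the empirical p is two-sided on |ES| with +1 smoothing. Set-size
  bounds default to 10–500.
* **ORA** (`hypergeomORA`): upper-tail hypergeometric with BH across
  sets; gene ratio = overlap / hits.
* **Developmental delay**: the E3.5 summary of a feature is
  max(ICM, trophectoderm) TPM; the developmental log2FC is
  0.75·(TE vs 8-cell) + 0.25·(ICM vs 8-cell); Pearson correlations are
  reported both for significant features and for all features, and mean
  trajectories carry a basic nonparametric bootstrap 95% CI
  (`bootstrapMeanCI`, percentile interval).
* **Classical tests**: the chi-squared comparison of observed genotype
  counts against theoretical Mendelian ratios is implemented as a
  goodness-of-fit test (the figure construction), with a separate
  independence mode for contingency tables — the source text labels it
  a test of independence while comparing against fixed ratios, an
  ambiguity we resolve in favour of the construction actually shown.
  Wilcoxon rank-sum (exact for tie-free data, corrected normal
  approximation otherwise), two-sided Fisher exact, and Welch t-tests
  wrap the base R implementations behind validated interfaces; the test
  suite checks each against full-enumeration oracles on small inputs.

# The synthetic-data generator

`SimConfig` fixes the study conditions; every generator derives an
isolated RNG stream from the master seed and a fixed label, so adding a
generator never perturbs existing outputs, and identical configurations
are byte-identical.

* **Toy annotation** (`makeToyAnnotation`): random-sequence genome (no
  biological realism claimed — only interval and sequence mechanics
  matter downstream) with non-overlapping repeat elements (500–3000 bp)
  and gene bodies (1–4 kb), plus designated Y-linked, mitochondrial and
  rDNA-proxy genes and one autosomal mutation-target gene whose central
  codon carries the substitution/deletion alleles.
* **Fragments** (`simulateFragments`): fragments are drawn per feature
  proportionally to rate × length; per-sample Gamma rate noise with the
  config's NB dispersion makes counts marginally negative-binomial
  across samples (without it, fixed-depth multinomial sampling is
  unrealistically tight and small compositional shifts reach
  significance). A configurable fraction of repeat fragments straddles
  element boundaries to exercise the containment filter; DNA
  contaminants are drawn uniformly over DNA-class elements; deletion
  reads over the codon are emitted as match + soft-clip records.
  Internally the generator works on GRanges (1-based closed); emitted
  SAM follows the 1-based convention and BED export is 0-based
  half-open, with the conversions unit-tested at the I/O boundary.
* **Counts** (`simulateCounts`): NB(mean = baseline × 2^(lfc·group) ×
  2^(batch term) × size factor, dispersion α) with log-normal baselines
  around 100, one latent batch factor with per-gene loadings U(0.5, 1.5)
  and per-sample values N(0, 1), and size factors U(0.7, 1.4).
* **Embryo cohorts** (`simulateEmbryoCohort`): Y-gene counts Poisson at
  rate 30 (males) vs 0 (females, plus optional noise), mt/rDNA count
  fractions set per config (deliberate outliers possible), tag reads
  Poisson(500) for tagged vs Poisson(2) for WT embryos, codon reads per
  the allele mixture.

Defaults chosen once for the synthetic study conditions: 10 samples per
group (the blastocyst comparisons used 9–10 embryos per genotype),
dispersion 0.05 (typical for isogenic single-embryo libraries at these
depths), DNA contamination fraction 0.05, depth 20,000 fragments per
library for the fragment-level stages and 2,000 genes at most for the
count-level stages — problem sizes at which every statistical property
the tests assert (calibration, power at log2FC = 1, factor recovery) is
already stable. What the generator does *not* emulate: sequencing error
and quality scores, full CIGAR grammar beyond match + soft-clip,
transcript isoforms, positional coverage bias, and mappability
structure. Passing tests therefore demonstrate the correctness of the
implemented procedures under the stated model, not robustness to
artefacts absent from the model.

# Workflows

`runEmbryoWorkflow` chains cohort simulation → QC → sexing/genotyping →
gene DE (RUV-adjusted when batch structure is present) → SAM-level
repeat quantification with the DNA covariate → repeat DE (repName and
family level) → ranking/GSEA/developmental-delay statistics, writing
flat TSVs plus a JSON report with a determinism hash (md5 over the
sorted per-file md5s). Genes are called at padj < 0.05 and repeats at
padj < 0.1, the study's thresholds; both are configurable.
`runBulkWorkflow` runs the placenta-style design: validation that
metadata carries sex and genotype, sex-stratified genotype DE, a
sex-contrast analysis, marker-set GSEA and the repeat stage. Any stage
failure aborts with the stage name, keeping partial outputs. The
exported functions are the package's interface; a thin wrapper script
(`inst/scripts/run_pipeline.R`) runs either workflow from a YAML config
for shell use.

# Known limitations

* The DE engine approximates, not replicates, the published moderated
  dispersion estimator; the t-reference Wald p is deliberately
  conservative at very small n.
* Per-insertion repeat quantification and EM reassignment of
  multimappers are out of scope; quantification is repName-level only.
* The sexing threshold and embryo outlier rules are reproducible proxies
  for decisions the original analysis made by inspection; their defaults
  are documented above and configurable.
* GSEA set databases, GO semantics and term simplification are not
  provided; the gene-set interface is generic (named lists / GMT-style).
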
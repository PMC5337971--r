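---
title: "Functional fine-mapping of a regulatory risk locus under aneuploidy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional fine-mapping of a regulatory risk locus under aneuploidy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulomap)
```

# The analysis chain

`regulomap` implements, as tested reusable code, the complete computational
chain of a post-GWAS functional fine-mapping study of a regulatory risk
locus in a hyperdiploid leukaemia setting:

1. **Association and meta-analysis.** Per-SNP additive logistic regression
   of case status on allele dosage; fixed-effects inverse-variance pooling
   across studies.
2. **Risk-haplotype selection.** Composite LD ($r^2$ of dosage vectors),
   threshold filtering on imputation quality (INFO), minor allele
   frequency, association $P$ and odds ratio, and prioritisation of the
   surviving SNPs by overlap with regulatory annotation tracks.
3. **Allele-specific binding (ASB).** Reference masking at known variants,
   pileup-based allele counting at a heterozygous SNP, exact binomial
   tests per ChIP-seq replicate, weighted Fisher combination, and a
   whole-genome-sequencing copy-number control.
4. **Chromatin contacts.** Knight-Ruiz balancing of a binned contact
   matrix, a per-distance expected model, observed/expected loop
   enrichment, and ranking of contacts within the anchor's TAD.
5. **Expression genetics under trisomy.** eQTL ANOVA restricted to
   trisomic tumours (gene-dosage control), B-allele-frequency
   classification of the duplicated homologue, the one-sided binomial
   preferential-retention test, and cross-cohort Spearman correlation
   combined by the weighted Fisher method.

Every stage consumes inputs generated by the package's own simulators,
which plant known effects and write a truth ledger, so the whole chain is
testable end to end without access-restricted data.

# Statistical models

## Association and meta-analysis

For variant $j$ with dosage $g_{ij} \in [0,2]$ the model is
$\operatorname{logit} P(y_i = 1) = \alpha + \beta g_{ij}$, fitted by IRLS
(the binomial GLM). Inference is Wald: $z = \hat\beta/\widehat{se}$, two
sided, matching standard GWAS software. Monomorphic variants are skipped
with an explicit status; quasi-complete separation ($|\hat\beta| > 15$) is
flagged rather than fatal. The meta-analysis pools $K$ studies with
weights $w_k = 1/se_k^2$:
$\hat\beta = \sum_k w_k \hat\beta_k / \sum_k w_k$,
$se = (\sum_k w_k)^{-1/2}$. Effects are harmonised by ref/alt match; a
swapped orientation is sign-flipped, but strand-ambiguous (A/T, C/G)
variants are refused rather than auto-flipped.

Filtering conventions follow the source conventions exactly: variants with
INFO strictly below 0.80 are excluded (so INFO = 0.80 is kept), while the
MAF, $P$ and OR filters are strict inequalities.

LD is the squared Pearson correlation of dosage vectors (composite LD).
Phase is unavailable in case-control dosage data, so this is an
approximation to haplotype $r^2$; for the simulator's haplotypes the two
coincide.

## Allele-specific binding

At a heterozygous SNP, each replicate's reference-allele count $x$ out of
$n$ informative reads (reads carrying neither allele never enter the
denominator) is tested against Binomial$(n, 1/2)$. The two-sided p-value
uses the minimum-likelihood method (the `binom.test` convention); the
difference from doubling the smaller tail is documented and tested.

Replicates are combined by Fisher's method,
$X = -2\sum_i \ln p_i \sim \chi^2_{2k}$, or its weighted Lancaster
generalisation in which $p_i$ is mapped through the upper quantile of a
Gamma(shape $= w_i k / \sum w$, scale 2), preserving the total $2k$
degrees of freedom; equal weights reduce exactly to Fisher. The pipeline
weights replicates by informative depth.

**Directional combination (a design choice).** Naively feeding two-sided
per-replicate p-values to Fisher's method has a known pathology: two
replicates imbalanced in *opposite* directions combine to "significant
ASB". The pipeline therefore defaults to the directional variant
(Pearson's method in Owen's formulation): combine the one-sided
p-values separately in each direction and report twice the smaller
combined value, capped at 1. This is a valid two-sided combined test —
its simulated null size is 0.034 at nominal 0.05 and 4×10⁻⁴ at nominal
0.001 — that rewards directionally consistent replicates. The naive path
remains available (`combination = "naive"`), and per-replicate two-sided
p-values are always reported. The sidedness of the combination is not
derivable from the source description, which reports only a combined
bound; both conventions are therefore exposed.

The verdict logic requires both a significant combined p *and* a clean
whole-genome-sequencing control (no allelic imbalance in input DNA, which
would indicate copy-number or mapping artefacts rather than differential
binding): `ASB` only when combined $p < \alpha$ and control $p >$
`control_alpha`; `control-failed` when the control itself is imbalanced;
`uncontrolled` when no control is supplied.

## Knight-Ruiz balancing and observed/expected enrichment

Balancing finds $b > 0$ with $b \circ (A b) = e$ so that
$\operatorname{diag}(b) A \operatorname{diag}(b)$ has unit row sums, via
the Knight-Ruiz inexact-Newton iteration with a conjugate-gradient inner
solve and an adaptive forcing term. Convergence is declared when
$\lVert e - b \circ (Ab) \rVert_2 <$ `tol` (default $10^{-8}$), so
retained row sums are constant to that tolerance. Bins with fewer than
`sparse_frac` (5%) nonzero entries are masked first: near-empty rows make
the problem ill-posed and are the standard failure mode of KR on sparse
matrices. Correctness is checked against an independent Sinkhorn-Knopp
iteration (agreement to $10^{-6}$ on random matrices).

The expected model is the standard observed/expected construction: the
expected value at bin distance $d$ is the mean of balanced entries over
all retained pairs at that distance, and the loop enrichment is
$\text{fold} = \text{balanced}[a,t] / \text{expected}(|a-t|)$. By
construction, per-distance sums of observed and expected agree.

**Known attenuation of the fold estimate.** Two small systematic effects
shrink the recovered fold below the planted value on a finite matrix: the
loop inflates its own distance stratum's mean (a $m/(m-1+f)$ factor for
$m$ pairs in the stratum), and under a $d^{-1}$ decay — whose row sums
diverge logarithmically — the balancing vector rises towards the matrix
edges, inflating stratum means relative to an interior pair. At the
default problem size (800 × 5 kb bins, see below) the noiseless recovery
of a planted 2.7-fold loop is 2.52. This attenuation is a property of the
accepted KR + O/E construction itself, not of the implementation; real
pipelines compute the expected curve over whole chromosomes, where the
first effect is negligible and the second is part of the definition.

TAD-contained profiles rank the anchor's fold against every retained bin
in its TAD. TADs are interior domains of roughly a megabase, so matrix
edge bins — whose balanced values are systematically inflated under the
power-law decay — never enter a profile.

## Expression genetics

Expression is analysed on the $\log_2(x+1)$ scale. The eQTL test is a
one-way fixed-effects ANOVA of expression on genotype class (risk-allele
count among the homologues present), restricted to tumours at a fixed
chromosome copy number — by default trisomic, which holds total gene
dosage constant so the genotype effect is not confounded with copy
number. A linear-trend variant is available behind `trend = TRUE`.
Degenerate inputs with no between-group variation return $F = 0$,
$p = 1$ explicitly.

On a trisomic chromosome a heterozygous SNP has B-allele frequency near
$2/3$ when the B homologue was duplicated and near $1/3$ otherwise. The
classifier calls the duplicated homologue by proximity: within `baf_tol`
(default 0.08) of a centre; otherwise ambiguous. The source material does
not state how duplicated homologues were called, so this operational
definition is the package's own; the retention statistic depends only on
the resulting counts. With the default BAF noise ($\sigma = 0.04$,
truncated Gaussian in $[0,1]$), misclassification is below 2% and
ambiguity below 10%. The retention test is the exact one-sided binomial
$P(X \ge k \mid n, 1/2)$ on unambiguous calls; ambiguous calls are
excluded from the denominator and reported.

Cross-cohort correlation uses Spearman's rank correlation with midrank
ties and the $t$-approximation on $n-2$ degrees of freedom (standard at
cohort sizes of tens to hundreds; an exact permutation option exists for
$n \le 10$). Cohort p-values, one-sided toward the common alternative,
are combined by the Lancaster-weighted Fisher method with sample sizes as
weights.

# The synthetic-data generators

The generators' defaults are the study conditions the workflow emulates;
they were fixed once and are not tuning knobs.

* **Case-control cohort**: 465 cases, 5,200 controls; an 8-SNP risk
  haplotype at MAF 0.33 with per-allele odds ratio 2.4; 50 unlinked
  background variants with uniform MAF in [0.05, 0.5] and imputation INFO
  in [0.55, 1]. Haplotypes are built by copying a founder allele with a
  per-SNP decoupling probability (default 0.01), giving pairwise
  $r^2 \approx (1-d)^4 \ge 0.88$ by construction — direct control of LD
  without coalescent machinery, which is out of scope. Case genotypes at
  the causal SNP are drawn from the case-ascertained distribution
  $\propto e^{\beta g} \binom{2}{g} p^g (1-p)^{2-g}$ (rare-disease
  limit), so retrospective logistic regression is consistent for $\beta$.
* **ChIP-seq replicates**: 3 replicates, Poisson mean depth 150, read
  length 36, planted non-risk:risk read ratio 1.7 at a heterozygous SNP
  mid-contig, optional flat per-base error rate (default 0). Reads are
  emitted pre-aligned (SAM) because alignment is out of scope; this
  isolates the counting logic.
* **Contact matrix**: off-diagonal expectation
  $c\,|i-j|^{-\gamma}$ with $\gamma = 1$; the anchor pair multiplied by
  2.7; Poisson noise on the upper triangle mirrored to preserve symmetry.
  Default 800 bins of 5 kb (a 4 Mb window) with the loop anchors 12 bins
  (60 kb) apart near the matrix centre — the anchor-to-promoter
  separation the workflow emulates. The scale $c$ defaults to
  $50\,(n_\text{bins}-1)^{\gamma}$ so even the sparsest distance stratum
  averages at least 50 counts per pair. The matrix length was chosen
  because the per-distance expected model needs many pairs per stratum
  and a small edge fraction for the fold estimate to behave like the
  whole-chromosome computation it stands in for; at 40 bins the estimate
  is visibly attenuated (2.33 of 2.7), at 800 bins it recovers 2.52
  (see the attenuation note above).
* **Tumour cohort**: 45 tumours, trisomic with probability 0.65 (so
  about 30 trisomic, the dosage-controlled analysis set); genotype drawn
  under Hardy-Weinberg at MAF 0.33 with the risk allele as the B allele;
  heterozygous trisomic tumours duplicate the risk homologue with
  probability 21/31; expression
  $= 5 - 0.6 \times (\text{risk copies}) + N(0, 0.35)$;
  BAF $= \text{(B copies)}/\text{(copy number)}$ plus truncated-Gaussian
  noise ($\sigma = 0.04$, typical SNP-array scatter). The effect size
  and residual SD encode a moderately strong eQTL: they were calibrated
  once so that the direction of the planted effect (decreasing
  expression with risk-allele count) is recoverable from ~30 trisomic
  samples in at least 95% of runs, and then frozen.
* **Expression cohorts**: paired bivariate-normal expression values with
  planted correlation 0.3 at cohort sizes 154, 92 and 139.

What the generators deliberately do **not** model: realistic coalescent
LD beyond the copy-with-decoupling block, base-quality-dependent error
profiles, mapping bias (reads are emitted pre-aligned), replicate-level
batch effects, contact-matrix features beyond a single power-law decay
plus one loop (no TAD-internal structure, no compartments), and
expression covariates (age, subtype, batch). Passing tests therefore
demonstrate correctness of the statistical machinery under the planted
models, not robustness to every real-data artefact.

# Numerical choices

* Logistic IRLS: deviance tolerance $10^{-10}$, max 50 iterations;
  separation flagged at $|\hat\beta| > 15$.
* KR: residual tolerance $10^{-8}$, max 1000 outer iterations, CG inner
  solve bounded by the Knight-Ruiz safeguards (delta = 0.1, Delta = 3),
  Eisenstat-Walker-style adaptive inner tolerance.
* Fisher combination refuses $p = 0$ rather than silently flooring;
  callers must floor explicitly at the machine minimum if they mean it.
* Bin assignment is half-open and offset-anchored: a position exactly on
  a boundary belongs to the higher bin. All internal interval arithmetic
  is 0-based half-open; VCF/SAM positions (1-based) are converted at the
  parsing boundary, so a variant at VCF position 100 overlaps BED
  interval [99, 100) and not [100, 101).
* Quality floors for allele counting (base quality 20, mapping quality
  10) are configurable defaults; the source states none.
* The pipeline's default fine-mapping thresholds are INFO $\ge 0.80$,
  MAF $> 0.01$, $P < 10^{-10}$, OR $> 1.5$. The stricter published
  thresholds ($P < 10^{-35}$, OR $> 2.4$) describe a meta-analysis over
  multiple cohorts; a single simulated cohort of 465/5,200 straddles
  them by sampling noise, so the defaults are set where the planted
  haplotype separates cleanly from the null background at this scale.
  All thresholds are plain arguments.

# Problem sizes used by the test and acceptance suites

Monte-Carlo checks run at the study's stated conditions: 200 seeds for
the ASB power and loop-recovery properties, 300 seeds for Wald CI
coverage at 465/5,200, 100 random matrices for the balancing oracle, and
200 seeds for the eQTL direction property. Property tests inside the
unit suite use smaller seed counts with correspondingly looser bands.

# Known limitations

* Composite LD approximates haplotype $r^2$; no EM phasing is attempted.
* No covariate adjustment or population-structure correction in the
  logistic model (out of scope).
* The duplicated-homologue caller is BAF-only; allele-intensity or
  sequencing-based calling would differ in its ambiguous zone.
* The O/E fold estimator carries the finite-matrix attenuation described
  above; at the default problem size it under-reports a planted 2.7-fold
  loop by about 0.18.
* Text formats only: dense/COO TSV contact matrices, SAM (not BAM/.hic).
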
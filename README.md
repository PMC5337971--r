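# regulomap

Functional fine-mapping of a regulatory GWAS risk locus under aneuploidy,
as a tested, reusable R workflow.

## The problem

Genome-wide association studies localise disease risk to haplotypes, not
mechanisms. For a regulatory locus the follow-up chain runs: confirm and
sharpen the association (logistic regression per SNP, inverse-variance
meta-analysis across cohorts), reduce the signal to a risk haplotype
(LD, imputation-quality/MAF/P/OR filters), prioritise candidate SNPs by
regulatory annotation, test whether a transcription factor binds the two
alleles unequally (allele-specific ChIP-seq read counts at a heterozygous
SNP, with a whole-genome-sequencing copy-number control), ask whether the
SNP physically contacts its target promoter (Knight-Ruiz-balanced Hi-C,
observed/expected loop enrichment within a TAD), test the expression
consequence in tumours while controlling gene dosage (eQTL ANOVA
restricted to trisomic blasts), and finally ask whether tumours
preferentially duplicate the risk homologue (B-allele-frequency
classification and a one-sided binomial test). `regulomap` implements
every step of that chain, plus seeded simulators that generate all inputs
with planted ground truth, so the whole pipeline is exercised and tested
end to end without access-restricted patient data.

It is written for statistical geneticists and computational biologists
who want the machinery of such a study as auditable, re-runnable code.

## The core statistics

* Additive logistic association `logit P(case) = a + b*dosage`, Wald
  inference; fixed-effects meta with weights `1/se^2`.
* Composite LD `r^2 = cor(dosage_a, dosage_b)^2`.
* Exact binomial test of allele-specific read counts against
  Binomial(n, 1/2); replicates combined by Fisher's method
  `X = -2*sum(log p) ~ chi^2_2k` or its depth-weighted Lancaster
  generalisation, with a directional two-sided variant as default.
* Knight-Ruiz matrix balancing (inexact Newton + conjugate gradients) to
  unit row sums; expected contact at distance d = mean balanced entry at
  d; loop fold = observed/expected.
* One-way eQTL ANOVA on genotype class in copy-number-restricted samples;
  one-sided binomial retention test `P(X >= k | n, 1/2)`; Spearman
  correlation with t-approximation, combined by weighted Fisher.

## Worked example

The `analysis/` directory holds the numbered drivers; each is a thin
narrative over package functions and writes its tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_association_finemap.R
Rscript analysis/03_allelic_binding.R
Rscript analysis/04_chromatin_contacts.R
Rscript analysis/05_expression_genetics.R
Rscript analysis/06_full_pipeline.R
```

At seed 1 the run prints:

```
simulated: 5665 samples x 58 variants; 3 ChIP replicates; 800x800 contact bins; 45 tumours (27 trisomic)
lead SNP hapSNP01: OR 2.310, p 9.29e-34
meta of 2 half-cohorts: OR 2.310, p 9.37e-34
LD to lead across the haplotype: r2 0.98-1.00
filter kept 8 of 58 variants (planted haplotype: 8)
top prioritised SNP: hapSNP01 (overlaps 6 of 6 tracks)
pooled fold 2.08 favouring T; combined p 1.63e-12; WGS control p 0.30; verdict ASB
KR balanced 800/800 bins in 36 inner iterations (residual 7.6e-09)
anchor bin 394 -> target bin 406: O/E fold 2.56 (planted 2.7)
planted partner ranks first in the TAD profile: TRUE (of 199 targets)
eQTL in 27 trisomic tumours: F = 41.48 on (3, 23) df, p = 1.92e-09
retention: 8 risk vs 3 non-risk duplicated (1 ambiguous), one-sided p = 0.113
reported 21:10 split gives one-sided binomial p = 0.0354
combined cross-cohort correlation p (weighted Fisher) = 0.000142
```

Reading the numbers: the cohort was simulated with a planted per-allele
odds ratio of 2.4 on an 8-SNP haplotype — the fitted OR of 2.31 is within
sampling noise, the meta of two half-cohorts agrees with the pooled fit,
and exactly the 8 planted SNPs survive the fine-mapping filters. The
ChIP-seq replicates were planted with a 1.7 non-risk:risk read ratio: the
pooled fold estimate is 2.08 favouring the non-risk T allele, the
combined binomial evidence is strong, and the balanced WGS control shows
the imbalance is not a copy-number artefact. The contact matrix carries a
planted 2.7-fold loop; the balanced observed/expected estimate recovers
2.56 and ranks the planted partner first among all 199 candidate targets
in its TAD. The planted negative eQTL effect appears as monotone
decreasing expression across risk-allele dosage groups in the trisomic
tumours. The cohort's own 8:3 duplication split is not significant at
n = 11 — small-sample honesty — while the reported 21:10 split gives the
one-sided binomial p = 0.035.

## Layout

```
R/                  package code: simulators, association/fine-mapping,
                    ASB, contact analysis, expression genetics, IO, the
                    pipeline orchestrator
analysis/           numbered narrative drivers (see above)
scripts/acceptance.R  headline-number reproduction
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette: models, design decisions, limits
```
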
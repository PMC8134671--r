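---
title: "Multi-tissue summary Mendelian randomization with smrmt"
author: "smrmt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tissue summary Mendelian randomization with smrmt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrmt)
```

## The model

Summary Mendelian randomization (SMR) asks whether the expression level of
a gene (the exposure, X) affects a disease phenotype (the outcome, Y),
using a genetic variant Z as an instrumental variable. Under the causal
chain Z → X → Y, the SNP's effect on the trait is the product of its
effect on expression and the expression effect on the trait, so the
quantity of interest is the Wald ratio

$$\hat b_{XY} = \frac{b_{ZY}}{b_{ZX}},$$

computable entirely from *summary* statistics: $b_{ZY}$ and its standard
error come from a GWAS of the phenotype, $b_{ZX}$ and its standard error
from a cis-eQTL study in some tissue. No individual-level data are
required, which is what makes the design practical: the GWAS and eQTL
studies are independent samples.

Two quantities accompany the estimate:

* a first-order delta-method standard error,
  $se_{XY} = |\hat b_{XY}|\sqrt{se_{ZY}^2/b_{ZY}^2 + se_{ZX}^2/b_{ZX}^2}$,
  evaluated in the algebraically equivalent form
  $\sqrt{se_{ZY}^2/b_{ZX}^2 + b_{ZY}^2\,se_{ZX}^2/b_{ZX}^4}$ so that
  $b_{ZY} = 0$ poses no difficulty (it reduces to $se_{ZY}/|b_{ZX}|$);
* the test statistic on the z-scores $z = b/se$,
  $$T_{SMR} = \frac{z_{ZY}^2\, z_{ZX}^2}{z_{ZY}^2 + z_{ZX}^2},$$
  referred to the upper tail of $\chi^2_1$. This is the form established
  in the SMR literature; a plain Wald test $(\hat b_{XY}/se_{XY})^2$ can
  be read off the reported columns, but the product form is the default
  because its null calibration does not depend on the delta approximation.

Two properties of $T_{SMR}$ matter in practice. First,
$T_{SMR} \le \min(z_{ZY}^2, z_{ZX}^2)$: the evidence for a mediated
effect can never exceed the evidence on either leg. Second, the statistic
is only asymptotically $\chi^2_1$ *given a strong instrument*: for
moderate $z_{ZX}$ the bound bites and the null rejection rate falls
slightly below nominal (at $|z_{ZX}| \approx 10$ the 5% test rejects
about 4.5% of the time). This is why instrument strength is screened
twice, and why the calibration checks below are run in a
strong-instrument regime.

## Assumptions and their failure modes

The single-instrument design inherits the classical instrumental-variable
assumptions: the SNP is associated with expression (relevance), and it
affects the trait only through the expression of the tested gene (no
horizontal pleiotropy). The second assumption is untestable with one SNP.
The package's generator can simulate the violation directly — a direct
SNP-on-trait effect $\theta$ that bypasses expression — and the test
suite documents that the SMR test then rejects far above nominal: a
significant SMR result means *association through a shared variant*, not
proven causality. Distinguishing pleiotropy/linkage from causality needs
additional machinery (heterogeneity tests across multiple cis-SNPs),
which is deliberately out of scope here.

## The pipeline

`runPipeline()` chains the stages; each is usable on its own.

1. **Reading and screening** (`readGwas()`, `readEqtl()`). Tab-separated
   tables with one header row; a *dialect* maps header names to fields so
   COJO-style `.ma` GWAS files and GTEx significant-pair exports (compound
   `chr_pos_ref_alt_build` variant ids) are both readable without code
   changes. Every row is screened against the field invariants
   ($se > 0$, $p \in (0,1]$, distinct alleles, allele frequency in
   $[0,1]$); rejected rows are tallied by reason, never silently dropped,
   and accepted + rejected always equals the input row count. Odds ratios
   are converted to log-odds at load because the ratio estimator needs
   additive-scale effects.

2. **Harmonization** (`harmonizePair()`, inside `selectInstruments()`).
   The two studies may report effects for opposite alleles or opposite
   strands. With the GWAS orientation as reference: matching pairs pass
   unchanged; swapped pairs (including swapped-on-the-other-strand)
   negate the eQTL effect; strand-ambiguous A/T and C/G SNPs are dropped
   whenever the effect-allele frequency is missing or within
   $[0.42, 0.58]$ — near 0.5 frequency carries no strand information, and
   with only one study's frequency available a palindromic SNP outside
   the band is taken at face value; irreconcilable allele sets are
   dropped. Harmonization is idempotent, and the whole analysis is
   invariant to simultaneously swapping alleles and negating effects in
   both input tables.

3. **Instrument selection** (`selectInstruments()`). One instrument per
   (gene, probe, tissue): the SNP present in both tables with the
   smallest eQTL p-value below `pInstrument` (default $5\times10^{-8}$,
   the conventional genome-wide threshold for a top cis-eQTL), ties
   broken by larger $|b/se|$ and then lexicographically smaller SNP id so
   selection is deterministic. A cis-window restriction (±1 Mb) applies
   only when gene and SNP positions are both known.

4. **Per-tissue testing** (`runTissueExperiment()`). Instruments with
   $|z_{ZX}|$ below `zxFloor` (default 1.96) are refused even if they
   passed the p-threshold under a different column convention — a weak
   denominator makes the Wald ratio explode. The family-wise error is
   controlled by Bonferroni: threshold $\alpha/n_{tested}$ with
   $\alpha = 0.05$ by default, configurable. (In the published gingivitis
   analysis this package re-derives, every reported p-value is below
   $3.03\times10^{-6}$, consistent with a Bonferroni-scale cutoff.)

5. **Cross-tissue aggregation** (`aggregatePairs()`,
   `crossTissueSummary()`, `snpRepetitionCounts()`). Significant results
   from all tissues are pooled into tissue-tagged (SNP, gene) pairs —
   probe-level duplicates collapse to the minimum p — and summarized as
   per-tissue distinct counts, a gene-by-tissue incidence map with
   genes-in-exactly-k-tissues counts, tissue-specific gene lists, and
   per-SNP repetition counts. The tissue-tagged pair is the counting
   unit: a gene significant in three tissues contributes three pairs.

6. **Over-representation** (`hypergeomEnrich()`), optional: a generic
   hypergeometric upper-tail test of a gene list against user-supplied
   term sets (two-column TSV or GMT), Benjamini–Hochberg adjusted. The
   plain tail is the default; the EASE variant (tail at one fewer hit) is
   available for comparability with DAVID-style tools but is not the
   default because the plain tail is the exactly testable standard form.
   The background is whichever universe the annotation supplies — whole
   genome versus expressed genes is the user's modelling choice.

## The bundled reference table

`gingivitisPairs()` returns the 26 significant SNP–gene pairs reported by
a published five-tissue SMR study of gingivitis, verbatim, with the
publication's short tissue labels normalized to GTEx names
(`Neuro` → `Nerve_Tibial`, `Artery` → `Artery_Tibial`,
`Skin` → `Skin_Sun_Exposed_Lower_leg`,
`Fibroblast` → `Cells_Cultured_fibroblasts`). Every count that study
derives from its table re-derives here exactly: the per-tissue SNP/gene
counts (4/5, 5/6, 5/5, 3/4, 4/6), the two genes recurring in four
tissues (FYCO1, FAM86C1), and the per-SNP repetition counts (rs72121193
nine times). That publication also notes two SNPs selected only once in
its repetition figure while six SNPs appear exactly once in its printed
table — the figure evidently counted probe-level duplicates that the
table collapses; `snpRepetitionCounts()` reports the verifiable row-level
quantity.

## The synthetic-study generator

`simulateStudy()` draws a complete study — one GWAS table, one eQTL table
per tissue, a truth table — at the *summary level*: observed effects are
normal draws around the truth with
$se = 1/\sqrt{2\,maf(1-maf)\,n}$, the standardized-trait approximation
that makes $se$ a deterministic function of allele frequency and sample
size. Simulating at this level (rather than via individual genotypes) is
exact for the quantities the pipeline consumes and fast enough for
thousand-gene calibration runs.

Defaults, chosen once as the study conditions the package is validated
under: eQTL $n = 1{,}000$ and GWAS $n = 100{,}000$ (typical for a single
GTEx tissue paired with a large case–control GWAS); minor-allele
frequency uniform on $[0.1, 0.5]$ (common variants, where the
standardized-trait $se$ approximation is accurate); true instrument
magnitudes $|b_{ZX}|$ uniform on $[0.5, 1.0]$ with random sign, giving
$|z_{ZX}|$ roughly 7–22 at the default eQTL size — cis-eQTLs strong
enough to pass $5\times10^{-8}$; one causal SNP per gene (the
single-instrument design); 30% of eQTL rows emitted in flipped allele
orientation so harmonization always has real work to do. The true
$b_{ZX}$ of a SNP is shared across tissues — each tissue observes it with
its own noise — so the single GWAS-side truth
$b_{ZY} = b_{XY} b_{ZX} + \theta$ is coherent; cross-tissue *effect
heterogeneity* is therefore not emulated, and cross-tissue overlap
statistics on simulated data reflect shared truth plus independent noise,
not tissue biology. The generator also makes no attempt at linkage
disequilibrium, realistic genomic coordinates, or multi-SNP genetic
architectures — passing tests demonstrate the statistical machinery, not
robustness to LD-confounded instrument selection on real data.

All randomness flows from the spec's single `seed`; the caller's RNG
state is saved and restored, and the same spec serializes to
byte-identical files.

## Numerical choices

* p-values from $T_{SMR}$ are computed in log space
  (`pchisq(..., log.p = TRUE)`); the `log_p` column is exact for
  arbitrarily extreme statistics and `p_smr` is floored at the smallest
  positive double rather than underflowing to 0.
* For files lacking a standard-error column, `zFromP()` recovers $|z|$
  from the two-sided p-value via the log-space normal quantile.
* Ties in instrument selection are broken deterministically
  (p, then $|z|$, then SNP id), so pipelines are reproducible without any
  RNG.
* Degenerate inputs fail loudly: $b_{ZX} = 0$ is a degenerate-instrument
  error, a p-value of 0 or a non-positive $se$ rejects the row at load,
  an empty instrument set yields an empty experiment (not an error), and
  an empty effective enrichment query is a usage error.

## Validation summary

The test suite validates the machinery at these problem sizes, chosen to
give tight Monte-Carlo error while keeping a full run under a minute:
null calibration on 5,000 null genes in the strong-instrument regime
(eQTL $n = 10{,}000$, so the $\min(z^2)$ bound is negligible); recovery
of $b_{XY} = 0.3$ across 1,000 causal genes at the default study sizes
(median within ±0.02); delta-method $se$ against the Monte-Carlo SD of
the ratio over $10^6$ draws for 100 strong instruments (within 5%);
statistic identities and the hypergeometric closed form against
exhaustive enumeration on universes up to 15. The same computations are
re-run from scratch by `scripts/acceptance.R`.

## Limitations

Single-instrument SMR cannot separate causality from pleiotropy or
linkage; no heterogeneity (multi-SNP) test is provided. No LD reference
panel is consumed, so instrument selection on real data should start from
pruned or fine-mapped eQTL exports. Binary summary formats (BESD) and
genome-build liftover are out of scope; inputs are plain tab-separated
text in the documented dialects.
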
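---
title: "Models and methods behind equidiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind equidiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`equidiv` implements the complete genomic-diversity workflow used for
multi-breed livestock studies on medium-density SNP arrays — developed around
the nine-breed horse setting of roughly 20 individuals per population and
~44k autosomal SNPs across 31 autosomes — as a tested, reusable pipeline.
This vignette explains the statistical models, the choices made where a
protocol leaves room, and what the synthetic-data generators do and do not
emulate.

```{r setup}
library(equidiv)
```

## Data model and quality control

Genotypes live in a `genotype_table`: an individuals × markers matrix of
counted-allele dosages (0/1/2, `NA` missing), a marker map (chromosome, bp),
and a population label per sample. PLINK text PED/MAP is the interchange
format; the PED family-ID column carries the population label, which is the
conventional slot for breed labels. The counted allele is defined as the
lexicographically smaller observed allele so that dosage coding is
deterministic whatever the file ordering; half-missing genotypes (`A 0`) are
treated as missing with a warning, matching common tooling.

Quality control mirrors the array protocol: markers on the X chromosome are
excluded, and SNPs with a call rate *strictly below* 0.90 are removed (a SNP
at exactly 90% survives). Both filters are idempotent and commute. When two
array panels are merged, only SNPs present on both are kept and dosages in
the second panel are flipped where the two panels count different alleles of
the same SNP; SNPs with disjoint allele pairs are rejected rather than
guessed at. Coordinates are 1-based inclusive bp throughout.

## Inbreeding from heterozygosity deficit

The excess-homozygosity coefficient for individual $i$ is

$$f_i = \frac{O_i - E_i}{L_i - E_i}, \qquad
  E_i = \sum_{j=1}^{L_i} \bigl(1 - 2 p_j (1 - p_j)\bigr),$$

with $O_i$ the observed number of homozygous SNPs, $L_i$ the number of
non-missing genotypes for $i$, and $p_j$ allele frequencies estimated from
**all samples pooled** — the whole-panel reference is deliberate, so $f_i$ is
comparable across populations (per-population frequencies can be supplied
through the `freqs` argument). The expression $1 - 2p(1-p)$ is symmetric in
$p \leftrightarrow 1-p$, so whether the counted or the major allele frequency
is used is immaterial. No small-sample correction is applied to $E_i$: some
tools use $2p(1-p)\,n/(n-1)$; this implementation follows the plain
expectation, a documented divergence. $f_i$ may legitimately be negative
(excess heterozygosity, typical of admixed or outbred individuals).

## Linkage disequilibrium

Pairwise $r^2$ is the squared correlation of allele indicators at the
haplotype level. Phase is unobserved in diploid data, so haplotype
frequencies are estimated by maximum likelihood with an EM step resolving
the only ambiguous class, double heterozygotes. Allele frequencies are
invariant under the EM update, so the fit is effectively a one-dimensional
maximization over the disequilibrium coefficient $D$; EM starts at linkage
equilibrium ($h_{AB} = p_A p_B$) and iterates to a $10^{-8}$
haplotype-frequency tolerance, at most 200 iterations. The test suite checks
the EM result against an independent grid search over $D$ to $10^{-6}$.
Monomorphic loci have no defined $r^2$ and propagate `NA`; they are excluded
from decay curves and never trigger pruning removals, which is logged rather
than silent.

LD decay bins all within-chromosome pairs by intermarker distance into
non-overlapping 10-kb bins (half-open, `[k·w, (k+1)·w)`) and reports mean
$r^2$ and mean distance per occupied bin.

LD pruning scans 100-SNP windows advancing 25 SNPs at a time within each
chromosome; inside a window, pairs are examined in marker order and when a
pair reaches $r^2 \ge 0.1$ the *later* SNP is removed, permanently. The
"remove the later" tie rule is a deterministic choice; windows never span
chromosome ends. The pruned panel feeds $f_i$, IBD, F~ST~, MDS, admixture
and the tree; ROH detection and LD decay always use the unpruned panel.

## Runs of homozygosity

The sliding-window caller reproduces the standard array protocol exactly: a
50-SNP window slides one SNP at a time; a window is homozygous when it has
at most 2 missing calls and no heterozygote; each SNP's score is the
fraction of windows containing it that are homozygous (interior SNPs sit in
exactly 50 windows, chromosome ends in fewer — the denominator is the
number of windows actually overlapping the SNP, which is the edge-correct
reading; an alternative fixed-50 denominator would only depress scores near
chromosome ends). A SNP with score ≥ 5% whose own call is homozygous and
non-missing is a segment candidate — requiring the SNP's own call keeps
heterozygotes out of reported segments, a stricter and deterministic policy
than window-level limits alone. Maximal candidate runs are split at
adjacent-SNP gaps above 5000 kb, then kept if they contain ≥ 50 SNPs, span
≥ 1 Mb, and average at most one SNP per 5000 kb (the density check applies
to the whole run; no re-splitting beyond the gap rule). Correctness is
defined by exact agreement with an exhaustive naive scanner on hundreds of
random fixtures.

The ROH-based inbreeding coefficient is
$F_{ROH} = \sum L_{ROH} / L_{AUTOSOME}$ with the array-covered autosome
length 2,242,939,370 bp as default denominator. Segments are classed short
(≤ 5 Mb), medium, or long (> 10 Mb); only the long cutoff is part of the
protocol, and the 5-Mb short bound mirrors the cattle-array comparisons this
classing is usually read against. Both cutoffs are arguments. A long run's
age is dated by inverting the expected IBD-segment length
$\ell = 100/(2g)$ cM: a 10-Mb run at the uniform 1 cM/Mb map dates to about
5 generations.

## Relatedness and structure

**IBS/MDS.** Pairwise identity-by-state is the mean shared-allele fraction
over loci non-missing in both individuals; the distance is $1 - IBS$.
Classical (metric) MDS double-centers the squared distances and
eigendecomposes; variance explained is each eigenvalue over the sum of the
*positive* eigenvalues (negative eigenvalues of non-Euclidean distances are
discarded from the accounting). Coordinates are deterministic up to per-axis
sign.

**Method-of-moments IBD.** Observed IBS-state counts are equated with their
expectations given IBD state (computed from reference allele frequencies,
without the small-sample correction factors of the original derivation),
solved sequentially for $P(IBD=0,1,2)$, truncated at zero and renormalized;
$\hat\pi = P(IBD{=}2) + \tfrac12 P(IBD{=}1)$. Truncation keeps estimates in
the simplex but leaves a small positive floor under the null (about +0.03
at 2,000 loci and 40 samples), so the untruncated `pihat_raw` is reported
alongside: it is the unbiased signed estimate and the one to average over
many pairs. Monomorphic loci are skipped; pairs with under 50 usable loci
warn.

**F~ST~.** Per SNP, the Weir–Cockerham (1984) two-population variance
components $a$ (among populations), $b$ (between individuals within), and
$c$ (within individuals) are computed from sample sizes, allele frequencies
and observed heterozygosity; the multi-locus estimate is the ratio of sums
$\sum a / \sum (a+b+c)$ — the standard weighting, with negative per-SNP
components retained (clamping would bias the combination). SNPs with a zero
denominator are excluded from both sums and counted.

**Admixture.** The K-cluster model
$g_{ij} \sim \mathrm{Bin}(2, \sum_k q_{ik} p_{kj})$ is fitted by plain EM —
not the block-relaxation acceleration of the dedicated tool — from a seeded
random start (Dirichlet(1) ancestry rows, Uniform(0.05, 0.95) cluster
frequencies). Five EM steps always run before convergence checking begins,
honoring the priming convention; iteration then stops on a relative
log-likelihood change below `tol`. The likelihood is monotone by
construction and asserted in tests. Cross-validation masks genotype
*entries* fold-by-fold and scores RMSE between observed and predicted
dosages $2\sum_k q_{ik}p_{kj}$. The dedicated tool scores a deviance-based
loss instead, so absolute CV errors are not comparable across
implementations — only the ordering over K is meaningful, and only that
ordering is asserted.

**Tree.** Neighbor joining (exact on additive matrices) runs on the same
$1-IBS$ distances as the MDS — the protocol's distance matrix is not
specified further, and using one metric for both keeps the two views of
structure consistent. Negative branch estimates are clamped to zero with the
deficit moved to the adjacent edge at the same node; raw lengths are kept as
an attribute. Trees are written as standard Newick.

## Synthetic data: what it emulates, and what not

The generators provide ground truth for every stage, standing in for the
array genotypes the pipeline was designed around (those are available only
on request, not deposited):

- `draw_balding_nichols()`: population allele frequencies
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ around a Uniform(0.05, 0.95)
  ancestral draw — the frequency bounds avoid monomorphic loci and are
  overridable. The target $F$ is exactly what the Weir–Cockerham estimator
  should recover, which closes the loop in the recovery tests.
- `simulate_unrelated()`: Hardy–Weinberg binomial genotypes, independent
  across loci, optional Bernoulli missingness (2% in the default desk
  fixture; observed panels stay under a 10% ceiling).
- `gene_drop()`: founders carry uniquely labelled whole-chromosome
  haplotypes; transmission is Mendelian with Poisson (Haldane, no
  interference) crossovers at a uniform 1 cM/Mb — the same implicit Mb↔cM
  equivalence the generation-dating argument uses. True autozygous tracts
  are maximal regions where both haplotypes carry the same founder label.
  The five-member full-sib pedigree (`fullsib_pedigree()`) gives the exact
  25% expectation for the grand-offspring, verified by path counting and by
  gene dropping.
- `wright_fisher_haplotypes()`: discrete-generation drift with
  recombination, generating genuine distance-dependent LD for the decay and
  pruning tests.

Not emulated: ascertainment bias of array SNP selection, genotyping error,
selection, non-uniform recombination maps, and realistic minor-allele
spectra. Passing recovery tests therefore demonstrates estimator
correctness under the stated models, not robustness to array design
artifacts — the same caveat that applies to the real arrays themselves.

## Problem sizes and numerical choices

The default desk-scale fixture is 3 populations × 20 individuals × 2,000
SNPs on two 100-Mb chromosomes; unit tests use smaller cuts (hundreds of
SNPs, tens of individuals) and the full suite completes in a few minutes.
Simulation-based assertions fix their seeds and state absolute tolerances
derived from Monte-Carlo standard errors (e.g. F~ST~ recovery at ±0.01 over
5,000 SNPs and 50 individuals per population; π̂ recovery at ±0.05 with a
five-chromosome, 600-Mb genome so genealogical variance does not swamp the
estimator). End-to-end pipeline runs in the test suite use K = 1–3 with 2–3
CV folds; the config defaults remain the full protocol (K = 1–15, 5 folds),
which is sized for a real dataset rather than a unit test.

Degenerate inputs are contracts, not surprises: an all-homozygous panel
makes $f_i$ undefined ($L_i = E_i$, reported `NA` with a warning); a
chromosome shorter than the ROH window scores zero everywhere with a
warning; a pair sharing no non-missing loci is an error naming the pair;
monomorphic SNPs propagate `NA` r², are skipped by IBD, and are excluded
from F~ST~ sums.

## Known limitations

- The PED parser accepts only biallelic SNPs and rejects a third allele.
- Admixture EM converges to a local optimum per seed; multiple restarts are
  the caller's responsibility (the fits are cheap and seeded).
- The method-of-moments IBD estimator assumes reference frequencies from a
  homogeneous pool; applying it across strongly diverged populations
  inflates apparent sharing, which is why the pipeline runs it on the
  pooled, pruned panel exactly as the protocol does.
- `pihat` (truncated) is the protocol quantity; `pihat_raw` is the
  unbiased one. Averages over many pairs should use the latter.
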
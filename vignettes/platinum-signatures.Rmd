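---
title: "Mutational signatures and recurrently mutated genes in chemotherapy-treated exomes"
author: "platisig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational signatures and recurrently mutated genes in chemotherapy-treated exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`platisig` implements the downstream analysis that turns a table of somatic
mutations from a small, heavily pre-treated tumor cohort into three kinds of
results:

1. **96-channel mutation catalogs** and cohort summary statistics
   (per-sample mutation rate, Ti/Tv ratio, VAF spectrum);
2. **de novo mutational signatures** by KL non-negative matrix
   factorization with bootstrap-stability model selection, annotated
   against reference profiles, with a dedicated score for the *platinum*
   signature (C>A transversions at CpCpA/CpCpG contexts);
3. **significantly mutated genes** via a convolution background test,
   with Fisher exact enrichment between response groups and against an
   external cohort.

A seeded synthetic-cohort generator with ground truth makes all of this
testable without any external download. Alignment, variant calling and
annotation are out of scope: the package starts from a MAF-like TSV.

# The 96-channel model

Every single-nucleotide variant is classified by its substitution type and
its 5'/3' flanking bases. Substitutions with a purine reference are mapped
to the reverse-complement strand, so the six types are C>A, C>G, C>T, T>A,
T>C, T>G; with 16 flank combinations each this yields 96 channels. Channel
order is substitution-major, then 5' base A,C,G,T, then 3' base A,C,G,T —
the de facto community convention — so bundled reference profiles align by
index. The mapping is total over all 192 stranded substitutions and
strand-invariant by construction (tested exhaustively). Contexts containing
ambiguous bases are excluded and tallied, never silently dropped.

Indels are excluded from the catalog (only SNVs have a trinucleotide
channel) but *included* in the mutation rate, which counts all coding
mutations over an exome of `exomeMb` megabases (default 30).

# Signature extraction

A cohort catalog $V$ (96 channels × $n$ samples) is modeled as $V \approx
WH$ with $W \ge 0$ the signature profiles (columns sum to 1) and $H \ge 0$
the exposures. We minimize the generalized Kullback–Leibler divergence

$$D(V \| WH) = \sum_{ij} \left( V_{ij} \log \frac{V_{ij}}{(WH)_{ij}}
  - V_{ij} + (WH)_{ij} \right)$$

by Lee–Seung multiplicative updates, which are monotone non-increasing in
$D$; the iteration stops when the relative objective change falls below
`tol = 1e-9` or after `maxIter = 10000` iterations. The inner loop is
compiled (RcppArmadillo). A small constant ($10^{-12}$) guards divisions
and logarithms; the monotonicity contract is asserted in the test suite on
every run within $10^{-8}$ relative slack. $W$ is initialized uniformly at
random from the run seed; $H$ is initialized deterministically from the
catalog column sums, which makes the whole iteration equivariant under
sample permutation (permuting samples permutes exposures and leaves
profiles unchanged up to floating-point summation order).

## Bootstrap stability and model selection

For a candidate signature number $k$, `extractSignatures()`:

1. redraws each sample's channel vector from a multinomial with the
   sample's original total ("multinomial bootstrap"; per-sample totals are
   conserved exactly, and resampling is keyed by sample *id* so it is
   invariant under sample reordering), `nBootstrap = 100` times;
2. factorizes every replicate and pools the $100 \cdot k$ replicate
   profiles;
3. partitions the pool into $k$ consensus clusters by iterative centroid
   reassignment under cosine distance, **with each replicate's $k$
   profiles matched one-to-one to the $k$ clusters** (greedy best-pair
   matching). The matching constraint matters: if $k$ exceeds the true
   signature number, the surplus profile differs from replicate to
   replicate and contaminates the clusters, which is precisely what makes
   the stability measure drop past the true rank. With free reassignment
   the surplus profiles can regroup into a spuriously coherent extra
   cluster. The partition is initialized from a factorization of the
   unresampled catalog (best of three restarts by objective);
4. reports the normalized cluster centroids as consensus profiles, the
   mean silhouette width of the pooled profiles under cosine distance as
   *stability* (per-cluster means are also reported), and refits the
   exposures to the original catalog with the consensus profiles fixed
   (non-negative KL fit, $H$-updates only). The reported reconstruction
   error is the generalized KL divergence of this refit.

At $k = 1$ the silhouette is undefined and stability is defined as 1: a
single cluster of bootstrap replicates is trivially reproducible. If a
cluster empties (not possible under matching with $\ge 1$ replicate, but
kept as a guard) the partition restarts with a jittered initialization up
to five times and is then flagged degenerate with stability $-1$ for the
empty cluster.

`selectK()` runs this for $k$ in `1:10` and selects the **largest $k$ with
stability ≥ `stabilityMin` (default 0.8)**, returning the full
(k, stability, reconstruction error) curve; if no $k$ reaches the
threshold, the argmax is returned and flagged. The threshold is explicit
and configurable because "stable" is not self-defining; 0.8 is a
conventional silhouette bar for tight clusters.

Signatures are ordered by total refit exposure and named `S1..Sk`.
Extracted profiles are annotated against a reference set by cosine
similarity (label assigned at cosine ≥ `minCos = 0.8`, ties to the first
reference, otherwise `"novel"`). The **platinum score** of a profile is
the summed weight on channels `C[C>A]A` and `C[C>A]G` — the
pyrimidine-strand image of adenine misincorporation opposite the 5'
guanine of Pt-GpG intrastrand adducts during error-prone translesion
synthesis. A uniform profile scores 2/96; the bundled platinum reference
scores about 0.78. What counts as "the" platinum signature is reported,
not decided: the score is returned for every profile and any
classification threshold is the user's.

## The bundled reference set

`inst/extdata/reference_signatures_synthetic.tsv` contains five *synthetic*
96-channel profiles (platinum, APOBEC-like, aging, UV-like, smoking-like)
constructed channel-by-channel to mimic the qualitative concentration
pattern of the corresponding processes (platinum: C>A at CpCpA/CpCpG;
APOBEC: C>T/C>G at TpCpW; aging: C>T at NpCpG; UV: C>T at dipyrimidines;
smoking: broad C>A). They are deliberately not copies of any published
signature catalog; pairwise cosine similarities are at most 0.17. Any user
reference table in the same layout can be substituted.

# Significantly mutated genes

Variants are first filtered to VAF **strictly greater than** 0.2 ("more
than 20%"): a variant at exactly 0.20 is excluded, and variants with
missing VAF are dropped and tallied. The rationale is that abundant
low-frequency variants reflect late, weakly selected mutational processes
and would swamp a recurrence analysis.

For a gene of coding length $L$ the mutation count contributed by sample
$s$ is modeled as $\mathrm{Binomial}(L, r_s)$, where $r_s$ is the sample's
per-base background rate (filtered mutations / exome size). The exact
null distribution of the cohort-wide total is obtained by convolving the
per-sample pmfs; since only mass below the observed total is needed, the
convolution is truncated there with no tail-mass loss, and
$p = P(\mathrm{total} \ge \mathrm{observed})$ is exact. This is a
single-category, coverage-free re-implementation of the MuSiC-style
convolution test: the original stratifies seven mutation categories and
uses per-gene covered bases from the BAMs, neither of which survives
downstream of a MAF. The simplification is documented as such; a
per-category extension would convolve category totals.

`smgScan()` tests genes mutated in at least `minPatients = 2` distinct
patients, adjusts by Benjamini–Hochberg over the tested genes only, and
reports genes with $q$ below `fdrMax = 0.2`. `subgroupDiscovery()` repeats
the scan per response group and reports genes significant in a subgroup
but not overall. Note the p-values are unconditional while testing is
gated on recurrence, so calibration statements are made over the whole
gene universe (untested genes implicitly $p = 1$), where the upper-tail
p-values are super-uniform.

Group enrichment uses the exact two-sided Fisher test with the
point-probability rule — the p-value sums hypergeometric probabilities of
all tables (margins fixed) whose point probability does not exceed the
observed one within relative tolerance $10^{-7}$ — not tail-doubling.
Patients are counted once per gene regardless of mutation multiplicity.
On the 3/7 vs 0/11 pattern this yields $p = 35/816 \approx 0.043$, and on
counts 3/18 vs 8/279 it yields $p \approx 0.023$; both round to the
two-decimal values a report would print. The implementation is verified
exhaustively against an independent binomial-coefficient enumeration over
all 2×2 tables with total ≤ 40 and spot-checked against
`stats::fisher.test`.

# The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with every default chosen once as a realistic study condition:

| parameter | default | rationale |
|---|---|---|
| samples / groups | 18, split 7 sensitive / 11 resistant | cohort design being emulated |
| load | log-uniform over 4.8–80.9 mutations/Mb × 30 Mb | spans the emulated cohort's dynamic range without assuming per-sample loads |
| signature mixtures | Dirichlet(0.6) over the 5 bundled profiles | per-tumor signature activity is sparse and heterogeneous in real cohorts; each process dominates a subset of tumors, which is also what makes the mixture identifiable to NMF |
| platinum VAF | Beta(1.2, 13) | ≈92% of platinum-origin mutations below VAF 0.2 (subclonal, treatment-late) |
| clonal VAF | Beta(6, 4) | clonal events well above the filter threshold |
| gene assignment | proportional to coding length; model sums to the exome size | keeps the per-gene null consistent with the per-base background rate |
| drivers | `(gene, group, prob` or `nPatients, mutationsPerPatient)` | planted with VAF > 0.2 so they survive the SMG filter; exact `nPatients` supports deterministic contingency fixtures |

Driver genes are excluded from background gene assignment so planted
contingency tables are exact. Contexts are generated directly on a random
strand (no reference genome); the FASTA path of `readMaf()` is exercised
with a tiny synthetic FASTA instead. The generator does **not** simulate
reads, purity/ploidy, indel contexts or clonal evolution, and its
exposures are free parameters never claimed to match any real cohort —
passing recovery tests shows the pipeline recovers *this* structure, not
that real tumors satisfy the model.

During development an alternative exposure default (near-uniform Dirichlet
skewed toward platinum) was found to produce realizations whose best
KL-objective factorization genuinely merges the flattest profile — an
identifiability failure of the data, not an optimizer artifact (verified
across restarts). Since the generator's purpose includes planted-structure
recovery experiments, the sparse symmetric Dirichlet was adopted as the
default; it is also the more realistic description of per-tumor signature
activity.

# Problem sizes used by the tests

The test suite and the acceptance script run entirely on generated data:
the default 18-sample cohort (~10–17k mutations depending on seed) for the
full $k = 1..10$, 100-bootstrap stability analysis; smaller 3-signature
cohorts at fixed loads of 200–600 mutations/sample for unit-level
extraction checks; a 3000-gene model (summing to 30 Mb) for SMG power and
calibration loops over 20 and 50 seeds; exhaustive enumerations for the
Fisher (all 2×2 tables with total ≤ 40) and channel-mapping (all 192
stranded cases) oracles; and Monte-Carlo checks at $10^5$ draws for the
convolution test.

# Known limitations

* The convolution background is single-category and coverage-free; genes
  with atypical context composition or coverage are mis-calibrated
  relative to the full MuSiC model.
* Stability-based selection inherits silhouette's biases; with very few
  samples the curve can plateau and the 0.8 bar is a convention, not an
  inference.
* The bundled references are synthetic stand-ins: annotation labels carry
  the meaning of the bundle, not of any published catalog.
* Exposure refitting attributes counts, not individual mutations; no
  per-mutation signature attribution is provided.

# A minimal session

```{r example}
library(platisig)

fix <- tempfile()
makeFixtureSuite(fix, seed = 1)

tab <- readMaf(file.path(fix, "cohort_main.maf.tsv"))
catal <- buildCatalog(tab)
sel <- selectK(catal, kRange = 1:10, nBootstrap = 100, seed = 1)
ann <- annotateSignatures(sel$extractions[[as.character(sel$k)]],
                          referenceSignatures())

rev3l <- readMaf(file.path(fix, "cohort_rev3l.maf.tsv"))
groups <- readGroups(file.path(fix, "cohort_rev3l.groups.tsv"))
rev3l <- MutationTable(mutationRecords(rev3l), groups = groups)
groupEnrichment(rev3l, "REV3L")
```
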
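---
title: "Deriving and validating DNA/RNA identification SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating DNA/RNA identification SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iisnp)
```

## The problem

Biomedical studies that pair DNA genotyping with RNA sequencing need a cheap,
robust way to confirm that a given RNA sample really belongs to the person it
is labelled with: sample mix-ups are common enough to corrupt eQTL and
association analyses, and forensic applications additionally want a minimal
marker set that identifies an individual from either a DNA or an RNA specimen.
Classical individual-identification SNP (IISNP) panels were chosen on DNA
data alone and are dominated by intergenic or lowly expressed positions, so
they genotype poorly from RNA-seq reads.

`iisnp` implements the complete workflow for deriving such a panel from a
cohort with *paired* DNA-based and RNA-based genotype calls, quantifying its
discriminative power, and then using it to detect mix-ups:

1. **Panel selection** — a filtering cascade over both call sets (call rate,
   biallelism, minor allele frequency, Hardy–Weinberg equilibrium, HLA
   exclusion, linkage-disequilibrium pruning), with a per-stage audit trail.
2. **Identity statistics** — per-locus and multilocus probability of identity
   for unrelated individuals (PI) and full siblings (PI-sibs), cumulative
   curves, and the minimum panel size that makes a cohort's members unique.
3. **Sample matching** — an allele-concordance score between every query
   (RNA) and reference (DNA/GWAS) sample over the panel, best-hit assignment
   against an expected mapping, and Passed/Failed/Unsure categorisation.

Because real cohorts of this kind are access-controlled, the package ships a
first-class synthetic-cohort generator with a known ground truth, so every
stage is testable end to end without any download.

## Statistical model

### Per-locus statistics

For a biallelic locus with non-missing genotype counts
$(n_{AA}, n_{Aa}, n_{aa})$ over $n$ samples, the package computes allele
frequencies by genotype counting, the minor allele frequency
$\mathrm{MAF} = \min_i p_i$, the call rate, observed heterozygosity
$H_o = n_{Aa}/n$, expected heterozygosity $H_e = 1 - \sum_i p_i^2$, and the
fixation index $F = (H_e - H_o)/H_e$ ($F$ is undefined, and flagged rather
than raised, at monomorphic loci). Missing calls are excluded from every
numerator and denominator.

### Exact Hardy–Weinberg test

Departure from HWE is tested with the exact conditional test: given the
observed allele counts $(n_A, n_a)$, every compatible heterozygote count $x$
(same parity as $n_A$, $0 \le x \le \min(n_A, n_a)$) has conditional
probability

$$
P(x \mid n_A, n) \;\propto\; \frac{2^{x}}{\left(\tfrac{n_A - x}{2}\right)!\,
x!\, \left(\tfrac{n_a - x}{2}\right)!},
$$

and the two-sided p-value is the total probability of all configurations no
more probable than the observed one (probability ordering). This is the
field-standard exact HWE test; it is conservative (true type-I error below
nominal) because the conditional distribution is discrete. The test suite
checks it against a full brute-force enumeration over genotype-count triples
for every total up to 30, and checks conservativeness on 2000 simulated null
loci. P-values are BH-adjusted across tested loci (`bh_adjust()`, a thin
wrapper over `stats::p.adjust`).

### Linkage disequilibrium

Because both call sets are unphased, $r^2$ between two loci is the squared
Pearson correlation of their alternative-allele dosage vectors (0/1/2) over
the samples where both are called — the composite genotype correlation, not a
haplotype-based measure. Pairs where either locus is monomorphic in the
shared-call subset carry no linkage signal and are treated as $r^2 = 0$.

Pruning is greedy: pairs at or above the threshold are visited in descending
$r^2$ order and the *less heterozygous* member of each still-intact pair is
removed (ties: lower MAF, then the lexicographically larger key). The order
and tie-breaks are declared choices — descending severity is reproducible and
removes the strongest linkage first; survivors provably satisfy
$\max r^2 <$ threshold, which the tests re-verify by recomputation.

### Probability of identity

For allele frequencies $p_i$ at one locus, the probability that two unrelated
members of a randomly mating population share a genotype is the sum of
squared HWE genotype frequencies

$$
\mathrm{PI} = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2 ,
$$

and for full siblings the standard full-sib match probability

$$
\mathrm{PI_{sib}} = \tfrac14 + \tfrac12 \sum_i p_i^2
 + \tfrac12 \Bigl(\sum_i p_i^2\Bigr)^2 - \tfrac14 \sum_i p_i^4 .
$$

The sib formula is not derived in the source literature for this workflow
(the original analysis delegated it to GenAlEx), so the package does not ask
you to trust it: the tests verify both formulas to $10^{-12}$ against
exhaustive enumeration — over all genotype pairs for PI, and over all
parental genotype pairs with their Mendelian offspring distributions for
PI-sibs — and additionally against Monte-Carlo simulation of a million
genotype pairs. PI-sibs $\ge$ PI always holds (relatedness can only make two
genomes more alike).

Multilocus values are products over loci (independence is exactly what the
LD filter is for) accumulated in log space, since a 50-SNP panel reaches
$10^{-20}$ and would underflow a naive running product long before that
became visible.

**Uniqueness criterion.** "How many SNPs make a cohort of $N$ unique" is
operationalised as the smallest $k$ for which the expected number of matching
sample pairs, $\binom{N}{2}\,\mathrm{PI}_{1..k}$, drops below one. The
criterion is reported alongside the result so alternative definitions can be
compared; with a constant per-locus PI of 0.375 (AAF 0.5) and $N = 2115$ it
yields $k = 15$.

### Allele-concordance matching

For a query and a reference genotype over the panel, each locus contributes
the size of the multiset intersection of the two unordered allele pairs
(AA–AA: 2, AA–AB: 1, AB–AB: 2, AA–BB: 0); the score is shared alleles over
total alleles (2 per compared locus — 100 alleles for a complete 50-SNP
panel). Loci with a missing call on either side are excluded from both sides
of the ratio; the number of compared loci is reported so the complete-data
denominator is recoverable. A query's best-hit set is every reference
attaining the maximum score, provided it reaches the threshold (default
0.8); multiple best hits are expected when the same person was genotyped
repeatedly. Categories: `PASSED_MATCHING` if any expected reference is a
best hit, `FAILED_MATCHING` if there are best hits but none is expected,
`UNSURE` if no reference reaches the threshold.

## The filtering cascade and its defaults

| Stage | Criterion | Default | Notes |
|---|---|---|---|
| call rate | RNA call rate strictly above | 0.90 | RNA calls are the scarce resource |
| biallelic | ≤ 2 observed alleles, ≤ 3 genotype classes | — | evaluated on RNA calls |
| MAF | strictly above, in **both** call sets | 0.20 | each set's own frequencies |
| common | locus present in both sets | — | (chrom, pos, ref) equal, alt sets overlap; REF conflicts are excluded and reported |
| HWE | exact p above `hwe_alpha` **and** BH q at least `fdr` | 0.01 / 1% | tested on DNA calls |
| HLA | outside chr6:28,477,797–33,448,354 (GRCh37 extended MHC) | on | calls there are artefact-prone |
| LD | pairwise $r^2$ strictly below | 0.01 | keep the more heterozygous member |

Three of these deserve comment.

* **HWE retention** applies both printed criteria (raw p > 0.01 and FDR 1%)
  as a conjunction. Since BH-adjusted values are never below raw p-values,
  the conjunction is equivalent to the raw-p rule alone; both sub-rules are
  nevertheless evaluated and independently switchable (`hwe_alpha = 0` or
  `fdr = 0`), so either printed interpretation can be reproduced exactly.
* **Which matrix feeds which test** is configurable. HWE defaults to the DNA
  calls (the less error-prone set); the biallelic/genotype-class screen runs
  on the RNA calls, where excess genotype classes actually arise; LD and the
  pruning heterozygosity default to DNA.
* **The LD threshold is a large-cohort setting.** The sampling null of $r^2$
  is $\approx \chi^2_1 / n$, so at $n = 2000$ samples an independent pair
  exceeds 0.01 with probability $\sim 10^{-5}$, while at $n = 100$ that
  probability is over 0.3 and the filter will prune heavily by chance. Use
  cohorts of at least several hundred samples, or raise `ld_r2`, when
  working at small scale.

There is no hard-coded "choose 50": the panel is whatever survives. An
optional `panel_size` cap keeps the most informative survivors (lowest
per-locus PI). A separate genetic-distance filter is not implemented; the
$r^2$ threshold subsumes the "close genetic distance" consideration, which
is a declared simplification.

## The synthetic cohort generator

`sim_config()` + `simulate_cohort()` generate a paired DNA/RNA cohort with a
truth channel. The generative model, and what it does and does not emulate:

* **Clean loci** draw genotypes independently per sample under HWE from a
  planted AAF, uniform on [0.25, 0.75] by default — comfortably inside the
  MAF > 0.2 regime the panel targets (the published panel's average MAF is
  0.35). Default cohort size is 2115 samples, the discovery-cohort scale.
* **Planted violations**: low-MAF loci (AAF in [0.05, 0.15]); three-allele
  loci with HWE multi-allelic genotypes; HWE-violating loci with
  inbreeding-like genotype probabilities $p^2 + f p q$, $2pq(1-f)$,
  $q^2 + f p q$ (default $f = 0.4$, which an exact test at $n = 2000$
  rejects with essentially full power); near-duplicate pairs (a copied
  column with a small per-sample re-draw rate, default 0.01 — sufficient to
  exercise a genotype-based $r^2$ filter without haplotype simulation);
  loci placed inside the HLA interval; and loci with depressed RNA call
  rate.
* **Full-sib pairs** are simulated through two explicit HWE parents and
  Mendelian transmission; sibs share no missingness correlation (simplest
  model).
* **The RNA matrix** equals the true genotype layer plus an independent
  per-call symmetric mis-call (uniform over the other genotypes, default
  rate 0.02, consistent with the >90% per-SNP DNA/RNA concordance typically
  observed for well-behaved panel SNPs) plus independent missingness.
  It does not model allele-specific expression, coverage-dependent dropout,
  or SNP-specific error — real RNA-seq genotyping occasionally shows
  individual SNPs with much worse concordance than any symmetric-error
  model predicts, which is precisely why panels are validated per SNP.
* **Label swaps** cycle the RNA rows of `n_swaps` chosen samples while the
  expected map keeps the original pairing, so each affected query's true
  donor is present under another label; `n_swaps = 2` is a pairwise
  exchange.

Passing tests on these cohorts therefore demonstrates the *machinery* —
filters fire on what they should, the truth set is recovered, swaps are
flagged — under the model's assumptions (unstructured population, independent
loci apart from planted duplicates, symmetric errors). They do not establish
performance on real data with population structure, batch effects, or
expression-driven genotyping error.

## Numerical and degenerate-input choices

* Genotypes are unordered (phase is ignored everywhere; all statistics used
  are phase-free); half-calls such as `0/.` are conservatively treated as
  missing.
* $H_e$ uses the plain $1 - \sum p_i^2$ without the $n/(n-1)$ small-sample
  correction, matching genotype-counting practice in this workflow.
* The exact-test p-value sums configuration probabilities with a $10^{-9}$
  relative tolerance when comparing against the observed configuration's
  probability, so floating-point noise cannot split exact ties.
* Monomorphic loci: HWE p = 1, $F$ undefined (flagged), dosage-constant LD
  pairs r² undefined → 0 for pruning.
* An empty survivor set at any selection stage is a valid result (empty
  panel), not an error; a sample pair with zero comparable loci has an
  undefined score and is categorised `UNSURE`.
* Everything is deterministic given seeds: the simulation seed lives in
  `sim_config()`, and the only other stochastic step (random non-matching
  pairs for the matched/unmatched comparison) takes an explicit seed.

## Problem sizes used in the shipped checks

The test suite exercises the statistical properties at sizes chosen to make
sampling noise negligible relative to the asserted tolerances: enumeration
oracles on 1000 random frequency spectra (2–4 alleles), an exhaustive
exact-test sweep over all genotype triples with $n \le 30$ plus a
2000-locus null calibration at $n = 500$, Monte-Carlo identity checks with
$10^6$ pairs ($3\sigma$ binomial bands), planted-cohort recovery at
$n = 2000$ samples, and mix-up detection at 200 samples × 50 loci with a 2%
RNA error rate. One caveat is intentional: at $n = 2000$ a clean HWE locus
still has a ~1% chance of a raw exact-test p ≤ 0.01, so truth-recovery
checks derive the expected HWE survivors by independent recomputation
rather than pretending sampling noise does not exist.

## Limitations

* Match probabilities cover unrelated individuals and full sibs only; no
  parent–offspring or half-sib classes, and no $\theta$-correction for
  population substructure.
* Strand flips between call sets are not reconciled; loci whose REF alleles
  disagree at the same position are excluded and reported.
* Hard genotype calls only — no imputation dosages, no read-level evidence.
* The HLA default interval is GRCh37; supply your own `hla_interval()` for
  other builds.
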
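---
title: "LD-based effective population size and drift divergence times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-based effective population size and drift divergence times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldne)
```

## What the package computes

`ldne` infers demographic history from dense autosomal SNP genotypes in four
connected steps, plus a forward simulator that provides data with known truth:

1. **Ne through time from linkage disequilibrium.** Recombination erodes LD
   at a rate set by the genetic distance `c` between loci, while genetic
   drift regenerates it at a rate set by the effective population size. At
   drift-recombination balance the expected squared dosage correlation
   between two loci `c` Morgans apart is approximately

   `E[r^2] = 1/(alpha + 4 Ne c) + 1/n`,

   where `n` corrects for estimating `r^2` from a finite sample of `n`
   diploids and `alpha` is a structural constant (below). Because LD at
   distance `c` has a characteristic turnover time of roughly `1/(2c)`
   generations, the Ne recovered from distance category `c` is read as the
   effective size about `t = 1/(2c)` generations ago: tighter pairs look
   further into the past. Binning pairs into 250 overlapping distance
   categories from 0.005 to 0.25 cM (step 0.001 cM) therefore yields an Ne
   *trajectory* whose deepest usable category, at 0.25 cM, dates to 200
   generations before present and whose tightest categories reach tens of
   thousands of generations back.

2. **Long-term Ne.** The trajectory is summarised by its harmonic mean —
   the natural average for drift, because the variance of allele-frequency
   change compounds as `1/(2 Ne)` per generation and small epochs dominate.

3. **Divergence times from FST.** Between-population differentiation under
   pure drift accrues as `FST(T) = 1 - (1 - 1/(2 Ne))^T`, inverted as
   `T = ln(1 - FST) / ln(1 - 1/(2 Ne))` generations. Pairwise FST is the
   Weir-Cockerham (1984) two-population estimator computed from variance
   components, as a ratio of sums over loci (not a mean of per-locus
   ratios), with observed heterozygosity taken from the genotypes so no
   Hardy-Weinberg assumption enters. Times in years use a configurable
   generation length, 25 years by default.

4. **UPGMA trees.** A divergence-time matrix is summarised as an
   ultrametric average-linkage dendrogram with merge height d/2, so node
   heights are half the pairwise divergence times, in years.

Regional subgroups are compared with the two-sided Wilcoxon-Mann-Whitney
rank-sum test on their per-bin Ne series (exact null distribution when
`n1 + n2 <= 20` without ties, otherwise a tie-corrected normal
approximation with continuity correction).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 2 | — | structural constant of the Sved relationship; 2 is the mutation-adjusted variant appropriate for SNP data, 1 the classic drift-only form. Both are exposed. |
| bin grid | 0.005–0.25 cM, step 0.001 | cM | 250 overlapping windows of width 0.005 cM; upper edges 0.001…0.250, lower edges truncated at 0; a pair on a shared edge enters both bins (closed intervals). |
| `1/n` correction | n = individuals | — | sampling floor of the composite (dosage) r² estimator; unphased genotypes are the input, so `n` is the number of individuals. |
| `generation_years` | 25 | years | calendar scaling of generations; 50 generations ↔ 1250 years. |
| QC thresholds | mind/geno 0.10, MAF 0.01, HWE 1e-4 | — | standard array QC; individuals are filtered before sites, and site statistics are recomputed after individual removal. |
| MAF floor for LD work | 0.05 | — | rare alleles carry little pairwise-r² information and systematically deflate mean r² (inflating Ne); the validation analyses therefore profile LD on MAF ≥ 0.05 sites, while `apply_qc()` keeps the looser 0.01 default for general QC. |
| pair-Ne rule | harmonic mean | — | the Ne entering the drift equation for a population pair; harmonic mean of the two long-term values (configurable to `min` or a fixed value). |

## Confidence intervals

Per-bin 95% intervals come from a leave-one-chromosome-out jackknife: each
chromosome's pairs are removed in turn, the bin's mean r² recomputed and
re-inverted to Ne, and the 2.5/97.5 percentiles of those re-inverted values
taken. Percentiles are used instead of classical jackknife pseudo-values
because pseudo-values can go negative on a strictly positive parameter;
the interval is widened minimally to bracket the point estimate so
`ci_low <= ne_hat <= ci_high` always holds. Long-term CI bounds are the
harmonic means of the per-bin bounds. Divergence-time CIs propagate only
the Ne uncertainty (the formula is re-evaluated at the Ne CI bounds); FST
sampling noise is not propagated, a documented limitation.

## The synthetic-data generator

`sim_wright_fisher()` runs a discrete-generation, random-mating diploid
Wright-Fisher population forward in time, one independently segregating
chromosome at a time: recombination between adjacent markers with
probability `d_cM/100` per meiosis (exact for the small intervals used),
founding standing variation with allele frequencies uniform on
[0.05, 0.95], and recurrent symmetric allele-flip mutation. Defaults
emulate a dense genotyping array: markers every 0.005 cM on 5 chromosomes
of 1.5 cM (300 loci each), 100 sampled diploids, and a burn-in of `4 Ne`
generations before sampling.

Mutation is on by default, with a per-locus rate scaled so that
`4 Ne mu = 0.1`. This is a deliberate design decision: without mutation a
finite population has no LD equilibrium — tightly linked variation
collapses onto a few haplotypes, mean r² at short distances keeps rising
toward 1, and surviving polymorphism is strongly biased — so the Sved
inversion has nothing stable to estimate at the deeper (tighter-linkage)
categories. With recurrent mutation the site-frequency spectrum and the
r²-vs-distance profile are stationary, which is also the regime the
`alpha = 2` (mutation-adjusted) default assumes. The pure-drift mode
(`mutation = FALSE`) remains available and is used in tests of linkage
structure, and `sim_split_drift()` — which validates the divergence
equation — is drift-only by design, exactly matching the pure-drift
accrual `FST = 1 - (1 - 1/(2 Ne))^T` that `divergence_time()` inverts.

What the generator does **not** emulate: real human genetic maps
(recombination hotspots), array ascertainment of SNPs, population
structure or migration within a panel, selection, and gene conversion.
Passing the recovery tests therefore shows the estimators are correct
under their own model assumptions at desk scale, not that field data meet
those assumptions.

## Numerical choices and degenerate inputs

* Bins whose adjusted r² (after the `1/n` subtraction) is non-positive
  carry no signal: Ne is undefined there and the bin is excluded from the
  harmonic mean. A negative Sved inversion is clamped to Ne = 0, and zero
  bins are likewise excluded (the harmonic mean is undefined at 0), with a
  warning either way.
* Negative multilocus FST estimates (sampling noise around zero) are kept
  in the FST matrix but clamped to 0 before the divergence logarithm;
  `FST >= 1` is an error (infinite time).
* Pairs monomorphic on their pairwise-complete subset are skipped and
  counted; loci monomorphic across a pooled population pair contribute
  nothing to either FST sum.
* UPGMA ties are broken deterministically by sorting labels
  lexicographically before clustering; a monomorphic HWE test returns
  p = 1; the HWE test is the 1-df chi-square without continuity
  correction, standard for array QC at these sample sizes.
* Sites are kept sorted by (chromosome, position); PLINK dosages count
  copies of the A1 allele (`.bim` column 5), and missing genotypes use the
  PLINK 2-bit missing code.

## Problem sizes used in the validation

The bundled analyses and tests run at desk scale, chosen so the full suite
completes in minutes: constant-Ne recovery uses Ne = 500 (and 200), 100
sampled diploids, 5 × 300 markers, 10 replicates; the split validation
uses Ne = 1000 per branch, T = 100 generations, 20,000 unlinked loci, 50
diploids per branch. At these sizes the harmonic-mean Ne lands within a
factor of two of truth and the recovered split time within 15% of truth —
the tolerances asserted in `tests/testthat/test-acceptance.R` and
recomputed by `scripts/acceptance.R`.

## Known limitations

* The deepest (tightest-linkage) bins are the least reliable: their
  `1/(2c)` time depths exceed the coalescent depth of any finite
  simulated population, and even at equilibrium the closed-form inversion
  is biased upward when `4 Ne c` is well below 1. The long-term harmonic
  mean is dominated by the better-behaved shallow bins, which is why it is
  the headline summary.
* Whether LD pairs should be pooled across chromosomes (done here) or
  averaged per chromosome is a convention; pooling weights chromosomes by
  their pair counts.
* The drift divergence equation assumes no migration and no post-split
  mutation contribution to differentiation; times for weakly diverged
  pairs are noisy in proportion to FST's sampling error, which the CIs do
  not capture (Ne-only propagation).
* The rank-sum comparison treats per-bin Ne values as exchangeable
  observations; adjacent overlapping bins share pairs, so its p-values are
  anti-conservative under autocorrelation and should be read as a
  screening statistic, which is why a stringent alpha (0.001) is the
  default decision threshold.
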
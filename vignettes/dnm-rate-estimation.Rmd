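---
title: "Estimating de novo mutation rates from trio sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating de novo mutation rates from trio sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmrate)
```

## The problem

A de novo mutation (DNM) is a variant carried by a child but absent from both
parents' germlines. With roughly 70 point mutations expected per genome per
generation, DNMs are needles in a haystack of some 4-5 million inherited
variants and of genotyping error, so a naive count of Mendelian violations
over-estimates the rate by orders of magnitude, while conservative filtering
under-estimates it unless the denominator is adjusted for the genome fraction
where a DNM would actually have survived the filters. `dnmrate` implements
both halves of the problem for cohorts of father-mother-child trios
sequenced to high depth (about 50x): a strictly filtered Mendelian-violation
caller, and a probabilistic, depth-stratified estimate of the callable
genome that serves as the rate denominator.

## Candidate calling

A site enters the candidate set for family $f$ only if

* the cohort-level **site filter** passes (below);
* the child is called heterozygous with $GQ \ge 50$ and
  $DP \in [10, 120]$ (the *heterozygote filter*);
* both parents are called homozygous reference with the same GQ and DP
  bounds and **zero** reads supporting the alternative allele
  ($AD_2 = 0$, the *homozygote filter*);
* no sample outside the family carries a non-reference genotype call at the
  site. Missing genotypes outside the family are not treated as carrier
  calls.

All bounds are inclusive. Candidates are then partitioned by the child's
allele balance $AB = AD_2 / (AD_1 + AD_2)$: calls with
$AB \in [0.3, 0.7]$ (closed) are taken as genuine germline DNMs; the
remainder - empirically a second mode around $AB \approx 0.18$ - are
putative somatic (mosaic) variants or artifacts and are reported separately.
Homozygous-alternative children under double-HomRef parents are excluded:
they would require two independent hits and the callability model below
calibrates heterozygote calling only. Indels longer than 39 bp are out of
scope of the de novo indel analysis.

### The site filter

The site-level screen consists of two tests with known null distributions,
each thresholded on its p-value at a configurable $\alpha$ (default 0.01
each):

* an **exact conditional strand-bias test** (hypergeometric) on the 2x2
  table of reference/alternative reads by forward/reverse strand, aggregated
  over the cohort;
* a **read-position rank test** (two-sided Wilcoxon) comparing the
  within-read positions of reference- and alternative-supporting
  observations.

Because the tests' null rejection rates are known, the expected fraction of
genuinely good sites lost to this filter is, assuming independence,
$\alpha_{site} = 1 - \prod_k (1 - \alpha_k)$ (0.0199 at the defaults), and
this loss is credited back in the denominator rather than ignored. The
statistics are carried in VCF INFO fields (`SRF/SRR/SAF/SAR`,
`RPR/RPA`) because they cannot be reconstructed from GT/GQ/DP/AD; sites
without them pass with $p = 1$, so the filter degrades gracefully to a
no-op on VCFs lacking read-level annotations (with $\alpha_{site}$ then set
to 0 by configuring empty alphas).

## The callability denominator

Let $C_f(x)$ be the probability that a true DNM at position $x$ in family
$f$ would be called and survive every filter. Assuming the three members
are called independently,

$$C_f(x) = C^{het}\!\big(d(c,x)\big)\; C^{hom}\!\big(d(p,x)\big)\;
  C^{hom}\!\big(d(m,x)\big),$$

where $d(i, x)$ is individual $i$'s depth at $x$, $C^{het}(d)$ is the
probability that a true heterozygote at depth $d$ is called Het and passes
the heterozygote filter, and $C^{hom}(d)$ likewise for
homozygous-reference calls. Both curves are **calibrated from the cohort's
own data**:

* $C^{het}$: at sites where one parent is confidently homozygous reference
  and the other confidently homozygous alternative (parental
  $GQ \ge 50$), the child must be heterozygous barring de novo events, so
  every such child observation at depth $d$ is a Bernoulli trial.
* $C^{hom}$: at sites where both parents of a family are confidently
  HomRef, the variant is carried by another family, and - for SNVs - the
  site is in the known-variants list (a dbSNP stand-in, which guards
  against calibrating on artifacts), the child is truly HomRef and
  supplies the trial. Calibration uses children only; an option widens it.

Depth bins with fewer than `min_trials` (default 100) observations are
pooled outward with their nearest neighbouring bins (ties toward lower
depth) until the minimum is met; depths beyond the calibrated range clamp
to the nearest bin. The expected callable genome of a family is then
$\sum_x C_f(x)$, computed exactly from the family's joint depth histogram
(a breakpoint sweep over the three BED-like depth tracks - never a
per-position expansion; a brute-force per-position oracle verifies
equality in the tests).

The family rate estimate is

$$\hat\mu_f = \frac{N_f}{2\,(1 - \alpha_{site}) \sum_x C_f(x)},$$

with the factor 2 converting haploid positions to diploid site-generations.
The pooled estimate divides the summed counts by the summed denominators;
the per-family rates feed only the paternal-age regression. SNV and indel
rates use separately calibrated callability tables (the indel calibration
is restricted to indel sites and drops the known-variants requirement,
since indel databases are far less complete).

### Uncertainty and the age effect

Confidence intervals are exact Garwood (chi-square) Poisson intervals on
the mutation count, scaled by the denominator:
$[\,\chi^2_{\alpha/2}(2N)/2,\; \chi^2_{1-\alpha/2}(2N+2)/2\,]/D$. The
choice is deliberate: with counts as small as 70 the normal approximation
visibly misses, and the exact interval guarantees at least nominal
coverage (verified empirically over simulated cohorts). The paternal-age
effect is an unweighted ordinary least-squares fit of family rate on
father's age at the child's birth, reported as extra mutations per
nucleotide per year; a variant weighted by family denominators is available
behind a flag. A p-value is reported only with three or more families.

## Indel repeat context

Indels concentrate in repetitive DNA, and their false-discovery rate
differs sharply between repeat and non-repeat context, so each indel is
classified from the reference sequence 100 bp either side of its outer
coordinates:

* **HR** (canonical homopolymer run): the indel lies within a run of six
  or more identical bases and the inserted/deleted sequence consists solely
  of the run base;
* **HR_NC**: such a run overlaps, but the indel sequence contains other
  bases;
* **TR** (canonical tandem repeat): an overlapping array of a unit longer
  than 1 bp repeated at least $2 \times \text{UnitLength} + 5$ times
  (9 copies for 2 bp units, 11 for 3 bp);
* **TR_NC**: an overlapping multi-base array below that threshold;
* **NONE** otherwise. Precedence is HR > TR > HR_NC > TR_NC.

The detector finds **exact** maximal tandem arrays (units canonicalised to
their minimal rotation, periodic units suppressed, contained arrays with
longer units suppressed). Tandem Repeats Finder, which tolerates mismatches
within arrays, would count slightly more context; a `read_trf_dat()`
adapter accepts TRF annotations as a drop-in replacement where that
behaviour is wanted. For insertions, "within a repeat" means the insertion
point touches the array span; the repeated unit is not required to match
the inserted/deleted sequence for TR classes (that requirement applies to
HR only, where the canonical/non-canonical distinction encodes it).

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates a cohort with known truth so that every
pipeline stage is testable without access-controlled data. It emulates:

* per-sample piecewise-constant depth tracks (negative-binomial segment
  depths, mean 52x as in high-depth trio studies, dispersion size 10,
  mean segment length 1 kb) from which both the VCF `DP` values and the
  BED depth tracks derive, so numerator and denominator see the same
  depths;
* background polymorphisms transmitted Mendelian-correctly (allele
  frequencies uniform on [0.05, 0.95]), which populate both calibration
  classes; their density (default 1 site per kb) keeps well over 1000
  calibration trials per depth decile at the default scale;
* germline DNMs at rate $\mu$ (default $10^{-7}$ per nucleotide per
  generation at the reference paternal age of 28.5 years, with a linear
  age slope of $3.88 \times 10^{-10}$/nt/yr) and somatic candidates at
  0.44 of the germline rate, of the order seen in blood-derived trio call
  sets where low-balance candidates make up roughly a third of the total;
* a bimodal allele-balance truth: germline Beta(50, 50) centred at 0.5,
  somatic Beta(7.2, 32.8) with mean 0.18; observed `AD` values are
  binomial draws given depth and true AB;
* genotype quality synthesised deterministically as
  $GQ = \min(99, \mathrm{round}(5\,DP\,(1 - 2|AB - E[AB]|)))$, so GQ
  thresholds bind at low depth and callability genuinely depends on depth;
* stray alternative reads in homozygotes at a per-read rate of $10^{-3}$
  (exercising the $AD_2 = 0$ filter), optional depth-dependent call-failure
  curves, and a site-filter false-rejection probability $\alpha_{site}$
  emulated directly: a rejected good site is emitted with extreme
  strand-bias statistics, an accepted one with balanced canonical
  statistics. Emulating the rejection rate directly (rather than sampling
  null statistics and testing them) keeps the realised loss exactly at
  $\alpha_{site}$; the discrete exact test is conservative, and sampling
  from its null would make the $(1-\alpha_{site})$ denominator correction
  slightly liberal.

It does **not** simulate reads, linkage disequilibrium, sequence-context
mutation spectra, mapping artifacts, or repeat-dense reference sequence, so
passing tests demonstrate the correctness of the calling and estimation
machinery under the stated generative model - not robustness to alignment
error or to repeat-induced genotyping pathologies in real data, which the
conservative filters address only heuristically.

## Numerical choices and degenerate inputs

* Depth-bin pooling: outward expansion, nearest bin first, ties toward
  lower depth; a depth with no trials anywhere is fatal.
* `GQ` at threshold: the simulator rounds (not floors) the GQ synthesis so
  that exact-boundary products like $55 \times 10/11 = 50$ do not fall to
  49 through floating-point.
* Degenerate site-filter inputs (missing statistics, empty margins, all
  ties) yield $p = 1$: absence of evidence never rejects a site.
* Undefined allele balance (zero informative reads) is an error at
  classification time, not a silent class.
* Multi-allelic VCF records are skipped and counted, not split: splitting
  would change `AD` semantics mid-pipeline.
* Analysis is restricted to autosomes by default (rates are reported for
  the autosomal genome); `regions = "all"` overrides.
* The depth histogram is exact (breakpoint sweep); positions missing from
  a track count as depth 0 and overlapping intervals within one track are
  fatal rather than silently summed.

## Problem sizes used in the shipped checks

The bundled tests run the full estimator at 10 trios over a 10 Mb synthetic
autosome at $\mu = 10^{-7}$ (100 replicates for the parameter-recovery
check, which requires mean relative bias under 10%), interval coverage over
200 smaller cohorts, and the repeat classifier against an exhaustive
decomposition oracle over all two-letter sequences up to length 12 plus 500
longer sampled ones. These sizes were chosen to give the properties
meaningful statistical power at desk scale; the estimator itself has no
built-in scale assumptions and streams genome-scale depth tracks through
the same histogram sweep.

## Known limitations

* The callability model calibrates child-Het and child-HomRef calling and
  applies the latter to parents; a parent-specific bias (e.g. systematically
  different library quality) would propagate into the denominator.
* Somatic candidates are a by-product, not an estimand: low-AB mosaic
  variants that fail the conservative GQ filter are invisible, so the
  somatic candidate count is a floor.
* The exact-match tandem detector understates repeat context relative to
  mismatch-tolerant tools; use the TRF adapter for parity with
  TRF-annotated call sets.
* With ten families the paternal-age regression has little power; the
  slope's standard error is the honest summary, not its point value.
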
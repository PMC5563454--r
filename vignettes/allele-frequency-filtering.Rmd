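---
title: "Allele frequency thresholds for Mendelian variant filtering: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele frequency thresholds: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credaf)
```

## The problem

Reference cohorts of tens of thousands of exomes give robust frequency
estimates even for rare variants, but using them well requires a
disease-specific notion of "too common". A fixed cutoff (say, exclude
everything above 0.1%) is simultaneously too lenient for prevalent,
heterogeneous disorders and too aggressive for recessive ones. `credaf`
derives the cutoff from the genetic architecture of the disease and then
handles sampling noise in the reference cohort explicitly.

## Maximum credible population AF

For a dominant disorder, a causal allele's population frequency is bounded by

$$\mathrm{AF}_{\max} = \mathrm{prevalence} \times \tfrac{1}{2} \times
\frac{\text{max allelic contribution}}{\text{penetrance}}.$$

The three parameters, all dimensionless fractions:

* **prevalence** — population fraction affected, taken as the highest
  literature estimate (conservative: a higher prevalence loosens the
  threshold). Accepted as `"1/500"`-style strings anywhere.
* **maximum allelic contribution** — the largest share of cases a single
  variant can explain. For well-studied diseases this is the upper
  confidence bound of the most common causal variant's frequency in large
  case series (`max_allelic_contribution()`); for poorly characterised
  diseases it can be extrapolated from similar disorders (rounded *up*) or,
  conservatively, replaced by the gene-level contribution (minimal
  heterogeneity assumption).
* **penetrance** — probability a genotype-positive individual is affected.
  The default is 1, the conservative (tightest-threshold) choice; the
  shipped cardiovascular presets use 0.5, the lower end of reported
  penetrance for the exemplar variants. Because the intended default is a
  judgement call, penetrance is always an explicit, visible parameter, and
  both conventions are exercised in the test suite.

The factor ½ converts per-individual prevalence to per-chromosome frequency;
no correction is made for homozygous carriers, negligible at the frequencies
of interest. Results are capped at 1 rather than erroring so that extreme
exploratory inputs remain usable.

For a recessive disorder, assuming Hardy–Weinberg random mating and free
compound heterozygosity among a gene's pathogenic alleles, affected
individuals arise at rate $q^2 \times \text{penetrance}$ where $q$ is the
summed pathogenic allele frequency in the gene. With a **maximum genetic
contribution** $g$ (share of all cases attributable to the gene) this gives
$q = \sqrt{\mathrm{prevalence} \times g / \text{penetrance}}$, and a single
variant accounts for at most the allelic-contribution share of $q$:

$$\mathrm{AF}_{\max} = \sqrt{\frac{\mathrm{prevalence} \times g}
{\text{penetrance}}} \times \text{max allelic contribution}.$$

Placing penetrance inside the square root and the allelic contribution
outside is a modelling decision: penetrance acts on genotypes (pairs of
alleles), heterogeneity on individual alleles. It is the only placement
consistent with the recessive worked example regression-tested in the
package (ciliary dyskinesia, tolerated count 322 at 121,412 chromosomes).

```{r}
pcd <- disease_architecture("1/10000", "recessive", 0.57, penetrance = 0.5,
                            max_genetic_contribution = 0.09)
max_credible_af(pcd)
predict(max_credible_af(pcd), an = 121412)
```

## Sampling noise: the one-sided Poisson bound

We never observe a variant's true population frequency, only its allele
count AC among AN genotyped chromosomes, and at the relevant frequencies the
count is well approximated as Poisson with mean $\mathrm{AF} \times
\mathrm{AN}$. `max_tolerated_ac()` returns the count at the upper bound of
the one-tailed confidence interval: the smallest integer $k$ with
$P(X \le k \mid \lambda = \mathrm{AF}_{\max}\,\mathrm{AN}) \ge 0.95$
(confidence configurable). Filtering only above this bound keeps the
probability of discarding a variant whose true frequency is actually at the
threshold below 5%. Because the Poisson distribution tightens with sample
size, the bound is *relatively* more conservative where AN is small — a few
alleles in a poorly genotyped subpopulation never trigger filtering.

## The filtering AF and popmax

`filtering_af()` inverts the bound per variant: the largest frequency $f$ on
a grid of millionths with `max_tolerated_ac(f, an) < ac` (strict, matching
the decision rule below). Numerically the boundary is found in closed form —
the largest Poisson mean $\lambda^*$ with CDF at $ac-1$ still $\ge 0.95$ is
the lower 5% quantile of a Gamma($ac$) distribution — then snapped *down* to
the grid, with an explicit two-sided check so results are identical to a
brute-force scan in $10^{-6}$ steps (the test suite verifies this
equivalence exhaustively for AC 0–50 at three sample sizes, and verifies the
quantile itself against direct probability-mass summation on a mean ladder
0–400). Grid granularity and confidence are arguments, not constants.

Conventions fixed here:

* **Singletons:** AC ≤ 1 returns filtering AF 0 — one observation carries
  almost no information about true frequency, so such variants are never
  filtered.
* **Decision rule:** a variant is *filtered* when filtering AF ≥ maximum
  credible AF (boundary filtered), *retained* otherwise. Lower thresholds
  therefore filter supersets.
* **Popmax:** `popmax_filtering_af()` computes the per-population values for
  the five major continental populations (AFR, AMR, EAS, NFE, SAS) and
  takes the maximum — a variant common in any one well-sampled population is
  not a credible candidate regardless of its global frequency, provided
  prevalence and architecture are ancestry-stable. Populations with AN = 0
  (or below a caller-chosen `min_an`) are excluded rather than treated as
  frequency 0; ties go to the first population in canonical order.
  Bottlenecked populations (e.g. Finnish) and residual groupings are
  excluded from the default set because founder effects violate the
  architecture assumptions, but any label set can be whitelisted.

## VCF annotation

`annotate_vcf()` reads ExAC/gnomAD-style per-population `AC_*`/`AN_*` INFO
fields (key patterns configurable), decomposes multi-allelic sites with
allele-indexed values aligned to their alternate allele, and writes
`FAF95_<POP>`, `FAF95_popmax` and `FAF95_popmax_pop` INFO keys declared in
the header, at six decimal digits to match the default granularity. Records
with AC > AN in any population are skipped with a warning rather than
aborting a batch; records missing all mapped keys pass through flagged, with
popmax 0 (never filtered). Coordinates are taken as-is — no normalisation or
liftover — and identity is the textual (chrom, pos, ref, alt) key.
Homozygote counts, where present, are deliberately unused: the procedure
operates on allele counts only.

## Cohort statistics

* `proportion_ci()` defaults to the Wald interval
  $p \pm z\sqrt{p(1-p)/n}$ clamped to $[0,1]$ — the convention in which
  case-series frequencies accompanying architecture estimates are reported,
  and the one under which the package's preset parameters were derived.
  Wilson and Clopper–Pearson intervals are available by flag; they matter at
  very small counts, where Wald collapses (the 0/n interval is degenerate).
* `burden_odds_ratio()` uses the cross-product formula with a log-OR normal
  CI; the Haldane–Anscombe 0.5 correction is applied to the CI only when
  exactly one cell is zero, and flagged. A zero control-carrier cell yields
  an infinite, flagged point estimate.
* `bin_by_af()` stratifies variants into right-closed bins
  $(a, b]$ (default breakpoints $4\times10^{-5}$, $10^{-4}$,
  $5\times10^{-4}$, $10^{-3}$) with an overflow bin; the boundary
  convention is a package decision, fixed by unit test. Variants absent from
  the reference go to the lowest bin.
* `estimate_penetrance()` reconstructs penetrance as
  $\mathrm{prevalence} \times \mathrm{AF}_{\text{case}} /
  \mathrm{AF}_{\text{population}}$, capped at 1. Estimates exceeding 1 are
  capped *and flagged*: they indicate mutually inconsistent inputs, which is
  informative rather than an error. An estimate of exactly 1 is the
  compatibility boundary and is not flagged.

## The synthetic reference panel

`simulate_reference_panel()` exists so that every pipeline stage — VCF
parsing, popmax aggregation, filter decisions — is testable end to end
without reference downloads. It draws a global AF per site from a $1/x$
density truncated to $[10^{-6}, 0.5]$ (a neutral-like spectrum, heavy on
rare sites), perturbs it per population on the logit scale
(SD 0.5 by default — enough divergence to exercise popmax logic), and draws
each population's AC as Binomial(AN, population AF). Defaults are
desk-scale: five populations at 20,000 chromosomes each. Spiked
"pathogenic-like" sites have true AF 0 everywhere; in
`filtering_efficiency_experiment()` each simulated proband carries one of
them, emulating a causal variant absent from the reference, alongside
background variants carried with probability $1-(1-\mathrm{AF})^2$.
All output is byte-identical under a fixed seed.

What the simulator does **not** emulate: the empirical exome frequency
spectrum of real aggregation cohorts, linkage between sites, genotype-quality
based AC/AN adjustment (consumed as given), variant-effect classes, or
realistic demography (no coalescent). Passing tests therefore demonstrate
the *statistical* behaviour of the framework — calibration of the 5% bound,
monotone tightening of the filter, retention of reference-absent causal
variants — not the exact per-exome variant-count reductions achievable on
real exome data, which depend on the real spectrum.

Validation problem sizes, chosen as a balance the desk-scale generator
supports comfortably: panels of 80–2,000 sites, 500–50,000 chromosomes per
population, 20–25 held-out samples, $10^5$ Poisson replicates for the
error-rate check, and exhaustive grid-scan equivalence over AC 0–50 at AN
∈ {1,000; 10,000; 121,412}.

## Known limitations

The framework is an upper-bound argument, not a classifier: a variant below
threshold is merely *not excluded*. Its guarantees degrade where the
architecture is mischaracterised — founder mutations in bottlenecked or
under-studied ancestries can legitimately exceed the threshold, de-novo
dominant disorders are not modelled, and X-linked/mitochondrial inheritance
is out of scope. Penetrance is rarely known per variant; the
`implied_min_penetrance()` helper inverts the dominant model to show which
penetrance values remain compatible with an observed frequency instead of
pretending the answer is known. Reference cohorts may themselves be enriched
for late-onset conditions studied by contributing cohorts, in which case the
prevalence *within the cohort* should replace the population prevalence.
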
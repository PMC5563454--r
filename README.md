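# credaf — allele frequency thresholds for Mendelian variant filtering

Distinguishing disease-causing variants from rare benign bystanders is the
central bottleneck of Mendelian diagnostics: every exome carries thousands of
rare protein-altering variants, and "rare in the reference database" is a
necessary but weak criterion. `credaf` implements a statistically grounded
answer to the question *how common is too common for this disease?*, for
clinical geneticists and variant-curation pipelines working against large
reference cohorts (ExAC/gnomAD-style per-population AC/AN data).

## The model

**1. Maximum credible population AF.** A penetrant pathogenic allele cannot be
more frequent than the disease it causes, discounted by genetic heterogeneity
and inflated by incomplete penetrance. For a dominant disorder,

    AF_max = prevalence × 1/2 × max allelic contribution / penetrance

where the *maximum allelic contribution* is the largest share of cases any
single variant explains (estimated from case series), and the ½ converts a
per-individual prevalence to per-chromosome frequency. For a recessive
disorder, under Hardy–Weinberg mating with free compound heterozygosity, the
gene's summed pathogenic allele frequency is
`q = sqrt(prevalence × max genetic contribution / penetrance)` and a single
variant accounts for at most its allelic-contribution share of `q`.

**2. Maximum tolerated allele count.** An observed allele count in a finite
sample of AN chromosomes is Poisson with mean `AF_max × AN`; the maximum
tolerated AC is the count at the upper bound of the one-tailed 95% CI
(`qpois`). This keeps the false-filtering rate of genuinely pathogenic
variants at ≤5% even in small or poorly genotyped subpopulations.

**3. Filtering AF.** Inverting the bound per variant gives a disease-agnostic
annotation: the *filtering AF* is the highest threshold at which the variant's
observed AC would still be deemed too common (largest millionth-grid frequency
whose tolerated AC is below the observed AC). A variant is filtered for a
disease when its filtering AF ≥ the disease's maximum credible AF. The
*popmax* filtering AF takes the most extreme value across the five major
continental populations (AFR, AMR, EAS, NFE, SAS). Variants observed at most
once are never filtered.

## Worked example

Hypertrophic cardiomyopathy: prevalence 1/500, the most common causal variant
explains ≤2% of cases, reported penetrance 0.5.

```r
library(credaf)
arch <- disease_architecture("1/500", "dominant", 0.02,
                             penetrance = 0.5, disease = "HCM")
thr <- max_credible_af(arch)
print(thr)
#> Maximum credible population AF (HCM): 4e-05
predict(thr, an = 121412)
#> [1] 9
```

So a variant seen more than 9 times in 121,412 reference chromosomes is not a
credible HCM candidate (more than 5 times, if fully penetrant alleles are
assumed). Per-variant annotation runs the other way round:

```r
popmax_filtering_af(data.frame(population = c("AFR", "NFE"),
                               ac = c(0, 2), an = c(8000, 10000)))
#> Filtering AF (one-sided confidence 0.95)
#>   AFR  0
#>   NFE  3.5e-05
#>   popmax: 3.5e-05 (NFE)
```

This variant would be filtered for any disease whose maximum credible AF is
≤3.5×10⁻⁵ — not quite common enough to be excluded for HCM. Architecture
parameters themselves come from case series:

```r
round(proportion_ci(104, 6179), 4)   # most common variant in 6,179 cases
#> estimate    lower    upper
#>   0.0168   0.0136   0.0200
```

whose Wald upper bound (0.02) is the allelic contribution used above. Ten
ready-made architecture presets ship with the package
(`disease_presets()`), and `annotate_vcf()` / `filter_vcf()` apply the
popmax annotation and the ≥-rule decision to VCF files with per-population
`AC_*`/`AN_*` INFO fields. A command-line entry point (`exec/credaf`)
exposes every operation as a subcommand (`max-af`, `max-ac`, `filtering-af`,
`annotate`, `filter`, `case-ci`, `burden-or`, `penetrance`, `simulate`,
`presets`).

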
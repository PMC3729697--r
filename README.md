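# mitochron

Desk-scale phylogeography for human mitochondrial DNA: variant
nomenclature, haplogroup classification, maximum-parsimony haplotype
trees, and coalescence dating with a purifying-selection-corrected
molecular clock — built around the West-Eurasian haplogroups I (within
N1a1b) and W, with a coalescent simulator that makes every stage testable
against a planted truth.

## Who this is for

Population geneticists and ancient-DNA analysts who work with mtDNA
variant lists ("3447 8616T 16172"-style tokens relative to rCRS),
control-region (HVS-I) haplotype surveys, and clade age tables, and who
want the standard desk workflow — classify, build, date — as tested,
scriptable functions rather than spreadsheet arithmetic.

## The statistics at the core

For a clade with `n` sampled mitogenomes, the **ρ statistic** is the mean
number of substitutions from the clade's root haplotype to its samples;
its **heuristic standard error** is

    σ² = Σₑ nₑ² mₑ / n²

over the clade's edges (`mₑ` substitutions on edge `e`, `nₑ` samples
below it), which reduces to `σ = √(ρ/n)` on a star phylogeny.  A second
estimator fits a **clock-constrained Poisson maximum likelihood**: on the
fixed parsimony topology, node heights are chosen so that all
root-to-sample paths are equal and each edge's substitution count is
Poisson with mean equal to its height span.

Distances become ages through a **corrected molecular clock**: because
purifying selection removes mildly deleterious mutations slowly, the
observed substitution rate decays with age, and the conversion runs at
roughly 2.6 ky/substitution near the present versus ≈3.0 beyond ten
substitutions.  The package reconstructs this conversion by monotone
interpolation of the published (distance, age) anchor pairs for the I and
W trees (hotspot sites 16182C/16183C/16519 excluded throughout), and also
ships a parametric fit `d(t) = a·t + b·(1 − e^(−t/τ))`.  Confidence
intervals are `distance ± 1.96σ` converted through the clock; bounds
crossing zero convert to negative ages, as in the published tables.

## Worked example

Classify a published Corded-Ware-period HVS-I haplotype, then date a
simulated clade end to end:

```r
library(mitochron)

defs <- builtinHaplogroups()
anc <- variantProfile("esperstedt", c("16192", "16223", "16292", "16325"),
                      region = "HVS-I")
classifyProfile(anc, defs)
#> ClassificationResult 'esperstedt': W6 (score 2; matched 2, missing 0, private 2)

clk <- correctedClock()
round(clockConvert(clk, c(0.7, 6.8, 10.3)), 1)
#> [1]  1.8 18.4 28.6

# rho = 6.8, sigma = 0.8 (haplogroup W): age and 95% CI in ky
ageWithCI(new("AgeEstimate", clade = "W", method = "rho", n = 223L,
              distance = 6.8, dispersion = 0.8), clk)
#> W [rho]: 18.4 ky (95% CI 14.1; 22.8), distance 6.80 +/- 0.80

sim <- simulateClade(nTips = 5, tmrcaYears = 12000, seed = 42)
tree <- buildCladeTree(sim@profiles)
rhoSigma(tree)
#> AgeEstimate [rho] clade 1: n=5, distance=3.600, dispersion=0.980
```

The classification line reads: the haplotype matches both HVS-I-visible
mutations of the W6 cumulative motif (16292 from W, 16325 from W6) with
none missing; 16192 and 16223 are private at this resolution.  The clock
lines reproduce the published ages for those distances (1.8, 18.4 and
28.6 ky) and the W confidence interval {14.1; 22.8} ky.  In the simulated
clade, five samples carry on average 3.6 substitutions since a 12-ky-old
ancestor — `clockConvert(clk, 3.6)` ≈ 9.5 ky, within the CI implied by
σ ≈ 0.98 for so small a clade.

A thin command-line wrapper for the shell-facing operations is in
`inst/scripts/mito.R` (subcommands `variants`, `classify`, `survey`,
`tree`, `date`, `simulate`).

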
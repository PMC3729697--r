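---
title: "Dating and classifying mitochondrial haplogroups with mitochron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and classifying mitochondrial haplogroups with mitochron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochron)
```

## The problem

Human mitochondrial DNA is maternally inherited without recombination, so
its variation forms a single genealogy.  Clades of that genealogy
(haplogroups) are recognised by *motifs* — the mutations, written in
positional nomenclature relative to the rCRS reference, that accumulated
on the branch leading to the clade.  Two questions dominate the desk work
of mtDNA phylogeography: *which haplogroup does a sequence belong to*
(classification, often from no more than the first hypervariable segment,
HVS-I, positions 16024–16365), and *how old is a clade* (coalescence
dating from the number of mutations its members accumulated since their
common ancestor).  mitochron implements that workflow end to end for the
West-Eurasian haplogroups I (inside N1a1b) and W, together with a
simulator that generates clades with known ages so every stage can be
validated against a planted truth.

## Variant nomenclature

A variant token is a position with optional decorations: `16292` is a
transition, `8616T` a transversion to T, `249d` a deletion, `309.1C` an
insertion, and `195@` a back mutation toward the ancestral state.
`parseVariant()` normalises tokens and `profileFromSequence()` calls them
from aligned sequences; parsing and rendering are exact inverses on the
grammar.  Heteroplasmy and IUPAC ambiguity codes are rejected rather than
silently dropped — profiles are treated as consensus calls, and a
tolerant parser would blur the distance arithmetic downstream.

Indel placement in homopolymer tracts is alignment-dependent; we resolve
it by left-aligning gap runs, which is deterministic.  The community
convention for the mtDNA control region often names poly-C insertions
after the 3' end of the tract (e.g. 309.1C); since length variation
around 16182–16194 is masked for dating anyway and indels never enter the
distance computations, the choice of alignment side affects only the
token spelling, not any statistic.

Distances between profiles are masked symmetric differences.  The default
mask excludes exactly 16182C, 16183C and 16519, the conventional
exclusion list for whole-mtDNA dating.  The mask applies to distances and
dating only — classification motifs are matched unmasked, because a
classifier that cannot see 16183C would misread common control-region
haplotypes.

One deliberate narrowing: profiles carry a reference *name* and
operations refuse to mix references, but no rCRS-to-RSRS coordinate
translation table is shipped.  The authoritative difference list between
the two references is not reproducible from the material this package is
built on, and shipping an approximate table would corrupt profiles
silently.  All coordinates are rCRS-style throughout.

## Haplogroup classification

The shipped definition tree (`builtinHaplogroups()`) covers N, N1a1b and
its subclades N1a1b1 and I (I1–I7 with their named subclades) and W
(W1, W3–W7 with subclades), rooted at haplogroup N.  Motifs documented in
the literature are tagged `printed` or `curated`; for clades whose
defining mutations are not reproduced here, the table carries a synthetic
single-site placeholder marker in an otherwise unused coding-region range
(positions 5001 + 7k), tagged `placeholder` and flagged in the file name
(`haplogroups_iw_synthetic.tsv`).  Placeholders keep the tree
structurally complete — every named clade exists, every child differs
from its parent — without pretending to be real PhyloTree motifs.

A clade's *cumulative motif* is the union of branch motifs along its root
path, with back mutations cancelling earlier events at the same position.
A back mutation with no upstream event (the `195@` of the W motif, which
reverts a state older than the tree's root) simply drops out.

`classifyProfile()` scores each clade as `matched − missing` over its
cumulative motif, with both motif and profile restricted to the profile's
covered region (`full_genome`, `HVS-I`, or `control_region` — the D-loop,
16024–16569 plus 1–576).  The third region exists because published
ancient-DNA haplotypes typically cover both hypervariable segments: on
such data a full-genome scoring would penalise every coding-region motif
site as missing and collapse all calls toward the root.  Private variants
are not penalised; surveys and ancient samples are full of them, and they
carry no signal against a clade.  Clades whose restricted cumulative
motif equals their parent's are not separate candidates — within the
covered region they are indistinguishable, so the call stays at the
shallowest clade the evidence supports.  Remaining ties go to the deeper
clade, then to the higher stability-weighted match (hypermutable sites
such as 152 count half), then to the lexicographically first name.

```{r classify}
defs <- builtinHaplogroups()
classifyProfile(variantProfile("corded-ware",
  c("16192", "16223", "16292", "16325"), region = "HVS-I"), defs)
```

`surveyFrequencies()` tabulates per-population carrier percentages of a
clade's HVS-I motif.  Clades without any HVS-I component (W3 is defined
by a single coding-region transition at 1406) are flagged non-assessable
rather than silently reported as zero.

## Parsimony trees

`buildCladeTree()` merges identical masked haplotypes, absorbs changes
shared by all members into the stem, and recursively splits on the
unexplained variant shared by the most haplotypes.  Tie-breaking is
deterministic: carrier count, then site-stability weight (the shipped
hotspot list 146, 150, 152, 185, 189, 195, 204, 207, 309, 16093, 16129,
16182, 16183, 16189, 16192, 16311, 16519 at weight 0.5), then gains
before reversions, then lower position.  The published workflow this
mirrors used maximum parsimony followed by hand-correction against
PhyloTree; the weight table is a reproducible surrogate for those
editorial choices, not a reconstruction of them.

On homoplasy-free input the construction is a perfect phylogeny and
provably attains the optimal parsimony score (one event per distinct
variant); the test suite verifies equality with exhaustive search over
all topologies on instances of up to six tips.  With homoplasy the greedy
construction is a heuristic, like every practical parsimony method.  Two
invariants always hold and are property-tested: replaying edge mutations
from the root reproduces every input haplotype exactly, and duplicated
haplotypes never change topology or score.  Reversion events (rendered
`@`) can appear on edges through replacement states; the builder prefers
parallel placement of a recurrent variant when the scores tie, so a
haplotype lacking a clade's defining variant attaches below the last node
it supports rather than acquiring a private back mutation — the same
reading the published trees give such samples (classified as `I*`-style
paraphyletic lineages).  `homoplasyScan()` reports every position hit on
two or more distinct edges, reversions included.

## Coalescence dating

Two estimators of the root-to-tip molecular distance are provided.

**Rho.** `rhoSigma()` computes the mean number of substitutions (indels
excluded) from the clade root to its samples, with the heuristic standard
error `sigma^2 = sum_e n_e^2 m_e / n^2` (edge counts `m_e`, samples below
the edge `n_e`).  Conditional on the genealogy this is the exact Poisson
variance of rho; it does not account for genealogical randomness, which
is why the literature calls it heuristic.  On a star tree it reduces to
`sqrt(rho/n)`.

**Clock-constrained ML.** `mlDivergence()` fixes the parsimony topology,
treats node heights as free parameters with all root-to-sample paths
equal (a strict clock), models each edge's substitution count as Poisson
with mean equal to its height span, and maximises the likelihood; the
standard error comes from the observed information.  This is a Poisson
count likelihood, not an HKY likelihood over full alignments: the
published ML divergences we calibrate against were obtained with a
rate-matrix machinery whose exact settings are not reproducible from the
published material, so the package states its own model openly and
validates it by parameter recovery on simulated clades (estimate within
two standard errors of the truth in ≥90% of replicates) and by exact
agreement with rho on star trees.

**The corrected clock.** Purifying selection removes mildly deleterious
mutations over time, so young clades show more mutations per unit time
than old ones and the substitutions-to-years conversion is non-linear.
`correctedClock()` reconstructs this conversion from the published age
tables for the I and W trees, every row of which was produced by one and
the same corrected clock: each printed (distance, age) pair — and each
CI-endpoint pair implied by distance ± 1.96 × dispersion — is a point on
the curve.  Direct pairs are weighted by inverse squared printed
dispersion (floored at 0.15 substitutions, since a rounded "0.0" is not
infinite precision); CI-endpoint pairs carry a homoscedastic distance
error dominated by dispersion rounding, so they enter at flat weight and
only in gaps at least 0.1 substitutions from any direct anchor.  The
weighted pairs are aggregated per distance, monotonised by weighted
pool-adjacent-violators, and interpolated with a monotone Hermite spline,
linear beyond the last anchor (≈16.8 substitutions) and odd-extended for
the negative distance bounds that normal-theory CIs can produce.  The
resulting pace runs from ≈2.6 ky per substitution near the present to
≈3.0 near ten substitutions.

The printed tables are internally inconsistent at their own rounding
resolution — the same distance occasionally maps to two different rounded
ages (7.4 → 20.1 in one table, 20.3 in the other; 4.3 → 11.3 and 11.5) —
so no single-valued clock can reproduce *every* row to ±0.1 ky.  The
calibration reproduces its aggregated anchors exactly, the headline
anchor conversions to ±0.05 ky, and the full set of printed rows with a
median residual well under 0.05 ky and a maximum of ≈0.3 ky; the test
suite asserts exactly that attainable contract.

A second construction, `correctedClock("parametric")`, fits the
three-parameter purifying-selection form `d(t) = a·t + b·(1 −
exp(−t/τ))` — a constant neutral accumulation rate plus an exponentially
decaying excess of young, not-yet-purged mutations — to the direct
anchors.  It is smoother but slightly less faithful to the printed
arithmetic; the model's provenance tag records which construction is
active, and the anchor-calibrated mode is the default.

`ageWithCI()` converts `distance ± 1.96 × dispersion` through the clock.
The 1.96 multiplier is normal theory, inferred from the published
interval arithmetic; lower bounds crossing zero are converted as-is by
default (published tables print negative lower bounds), with
`floorAtZero` available.  Ages print in ky at 0.1 resolution, matching
table precision.

```{r dating}
clk <- correctedClock()
round(clockConvert(clk, c(0.7, 6.8, 10.3)), 1)
ageWithCI(new("AgeEstimate", clade = "W", method = "rho", n = 223L,
              distance = 6.8, dispersion = 0.8), clk)
```

## The simulator

`simulateClade()` draws a Kingman coalescent genealogy, rescales it to a
known TMRCA, and evolves a random 16,569-base root sequence along it.
Each branch receives a Poisson number of mutations whose expectation
comes from the corrected clock itself (`D(t_old) − D(t_young)` with `D`
the inverse clock), so the simulated mutation density is exactly the
density the dating machinery assumes — the natural null model for
validating it.  Default conditions follow the study design the package
mirrors: whole-molecule pace of one substitution per ≈2.5–3 ky, hotspot
sites hit at 10× the base rate, a 5% transversion fraction (mtDNA is
strongly transition-biased), and clades of 50 tips at a TMRCA of 12 ky
for the coverage checks.  Mutated sites follow the hotspot-weighted
distribution with replacement; a second hit on an already-derived site
either reverts it (probability 1/2 for transitions, by two-state
symmetry) or moves to another base — reversions and recurrent hits arise
naturally from sequence evolution rather than being painted on.

What the generator deliberately does not emulate: population structure
and growth (the genealogy is a neutral constant-size coalescent),
selection, rate heterogeneity beyond the hotspot list, ancient-DNA
damage, and sequencing error.  Passing tests therefore demonstrate that
the estimators are correct *under the model they assume*, not that real
data meet those assumptions.

Problem sizes used by the validation suite: the tip-replay invariant runs
on 1,000 random instances; parsimony optimality on exhaustive
enumerations up to six tips; ML parameter recovery on 400 clades of 20
tips; rho-CI coverage on 200 clades of 50 tips at TMRCA 12 ky; the
two-branch Poisson-mean check on 10,000 replicates.  The heuristic sigma
is approximately calibrated, not exact — its nominal 95% intervals cover
the true TMRCA at very close to, but not guaranteed above, 90% (a
1,000-replicate estimate under the same conditions gives ≈90%), which is
precisely the behaviour the field attributes to it.

## Numerical and degenerate-input choices

Classification and tree construction are fully deterministic, with all
tie-breaks documented above.  The clock inverse is computed by bisection
to 1e-10 and round-trips to better than 1e-6 relative error.  Empty
profiles classify to the root with score zero; empty clades are an error
for both estimators; a single-sample clade returns its tip count as the
ML divergence with an undefined standard error rather than a fake zero.
Zero observed mutations give rho = sigma = 0 and a degenerate CI, which
is the honest statement that the data contain no time signal.

## Known limitations

The built-in definition tree is a scaffold for the I/W analyses, not a
PhyloTree import; placeholder motifs make deep full-genome classification
within unpublished subclades nominal rather than real.  The greedy
parsimony builder can be beaten by exhaustive search on adversarial
homoplasy-rich input.  The clock is calibrated on 0–17 substitutions;
beyond that it extrapolates linearly and says so in its anchors slot.
Bayesian skyline analyses and kriged frequency surfaces are out of scope.
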
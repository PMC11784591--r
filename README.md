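# argtrait

Quantitative trait simulation directly on ancestral recombination
graphs (ARGs).

Modern population-genetic simulators and ARG inference methods encode
genetic variation for very large cohorts as succinct tree sequences —
tables of nodes, edges, sites and mutations describing the ensemble of
correlated genealogical trees along a genome. For GWAS method
development one then needs phenotypes simulated on top of that
variation. Exporting a genotype matrix first is wasteful (and at
biobank scale, infeasible) and discards the ancestral detail the ARG
carries. `argtrait` simulates quantitative traits *on the ARG itself*,
never materialising genotypes: causal information is propagated through
the local trees, so carriers of a causal allele are found by subtree
traversal, back-mutations included.

## Model

Each trait is associated with one or more causal sites. At a causal
site with causal-allele frequency *p*, a raw effect size β is drawn
from a chosen distribution (normal, fixed, exponential, gamma,
student-t, or multivariate normal across pleiotropic traits) and
optionally rescaled by

    β ← β · (2p(1−p))^(α/2)

where α sets the strength of frequency dependence (α < 0 up-weights
rare variants; α = 0 leaves β unchanged). Every node of the local tree
that inherits the causal allele — i.e. descends from the causal
mutation and is not under a reverting back-mutation — has genetic value
β at that site. Under the additive model an individual's genetic value
*G* is the sum of its nodes' values over all causal sites (diploids own
two sample nodes; any ploidy, and pedigree individuals attached to
internal nodes, are handled the same way). Finally, environmental noise
*E* ~ N(0, V_G(1−h²)/h²) is added per individual, where V_G is the
population variance of *G* and h² the requested narrow-sense
heritability, giving phenotype *P = G + E*.

## Worked example

The built-in example ARG has three diploid individuals (six sample
leaves `a`–`f`), one site with ancestral state `A`, a mutation to `T`
above internal node `i`, and a back-mutation to `A` above leaf `e`:

```r
library(argtrait)
arg <- make_example_arg()
model <- trait_model("normal", mean = 0, var = 1)
sim <- sim_phenotype(arg, model, h2 = 0.8, seed = 42)
sim
#> <phenotype_sim> 1 causal site(s), 1 trait(s), 3 individual(s), h2 = 0.8
#> $trait
#> # A tibble: 1 × 7
#>   site_id position causal_allele raw_beta scaled_beta allele_freq trait_id
#>     <int>    <dbl> <chr>            <dbl>       <dbl>       <dbl>    <int>
#> 1       0       50 T               -0.184      -0.184         0.5        0
#> $phenotype
#> # A tibble: 3 × 5
#>   individual_id trait_id genetic_value environmental_noise phenotype
#>           <int>    <int>         <dbl>               <dbl>     <dbl>
#> 1             0        0         0                  0.0325    0.0325
#> 2             1        0        -0.367             -0.0820   -0.449
#> 3             2        0        -0.184             -0.0336   -0.217
```

The single eligible site was chosen causal with causal allele `T`
(sample frequency 0.5) and a draw of β = −0.184 from N(0, 1). Leaves
`c`, `d` and `f` inherit `T` (leaf `e` is reverted by the
back-mutation), so individual 1 (`c`,`d`) has G = 2β, individual 2
(`e`,`f`) has G = β, and individual 0 has G = 0; each phenotype is G
plus calibrated noise. `tidy(sim)`, `glance(sim)` and `autoplot(sim)`
expose the result tables and a summary plot; `sim_trait()`,
`genetic_values()` and `sim_env()` run the three stages separately, and
a thin CLI (`inst/cli/argtrait_sim.R`) drives the same pipeline from a
shell.

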
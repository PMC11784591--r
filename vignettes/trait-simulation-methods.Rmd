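---
title: "Simulating quantitative traits on ancestral recombination graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating quantitative traits on ancestral recombination graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argtrait)
```

## The model

`argtrait` simulates GWAS-style quantitative traits directly on an
ancestral recombination graph (ARG) stored as succinct tree-sequence
tables. The simulation has three stages, mirroring the standard
additive model:

1. **Causal sites and effect sizes** (`sim_trait()`). Causal sites are
   drawn uniformly without replacement from the *eligible* sites of the
   ARG — those where at least one derived allele segregates among the
   sample nodes, i.e. has sample frequency strictly between 0 and 1 —
   or supplied explicitly by the user. At each causal site one causal
   allele is chosen uniformly among the eligible derived alleles, a raw
   effect size β is drawn from the configured distribution, and the
   frequency-dependent scaling β·(2p(1−p))^(α/2) is applied with that
   site's causal-allele frequency p.
2. **Genetic values** (`genetic_values()`). At each causal site, every
   node of the local tree whose allele equals the causal allele carries
   genetic value β. An individual's genetic value G is the sum of its
   nodes' values across causal sites. Ploidy is implicit: an individual
   owns however many nodes the tables assign to it.
3. **Environmental noise** (`sim_env()`). Per trait, noise is drawn
   i.i.d. per individual from N(0, V_G(1−h²)/h²), where V_G is the
   population variance of G and h² the requested narrow-sense
   heritability; the phenotype is G + E. With these definitions the
   expected realised heritability Var(G)/Var(P) equals h².

`sim_phenotype()` composes the three stages under one master seed.

### Allele-state resolution and back-mutations

A node's allele at a site is the derived state of the most recent
mutation on its path to the local root (including mutations on the node
itself), or the site's ancestral state if the path carries none. A
back-mutation therefore silences the causal allele for its whole
subtree: carriers are exactly the nodes descending from a causal-allele
mutation and not under a later mutation to a different state. The
implementation finds carriers by preorder traversal from each mutation,
pruning wherever a nested mutation starts, so per-site cost scales with
the mutated subtrees rather than the whole tree; allele frequencies and
state maps share the same walk.

When several mutations sit on the *same node* at one site they are
ordered by their parent-mutation links when those identify a unique
chain tail, otherwise by mutation time (smaller = more recent); inputs
with neither are rejected as ambiguous rather than silently broken.

### Edge cases and conventions

- Coordinates are 0-based with half-open `[left, right)` edge
  intervals; site positions are real-valued and strictly increasing
  with site id, following tree-sequence conventions.
- Nodes not covered by any edge at a site (isolated nodes, and local
  roots) take the ancestral state unless they carry a mutation
  themselves. This matters only for unusual table configurations, but
  it is a documented, testable choice.
- Sites monomorphic in the sample (p ∈ {0, 1}) are never eligible:
  they carry no association signal and the frequency scaling is
  degenerate there (undefined for α < 0). Requesting more causal sites
  than are eligible is an error, not a silent truncation.
- p is computed over sample nodes only. Non-sample nodes that belong
  to individuals (pedigree-embedded ARGs) do receive genetic values and
  do contribute to their individual's G; frequency, however, is a
  sample-level quantity in the GWAS model.
- Individuals with no carrier nodes — or no nodes at all — are
  reported with G = 0 rather than dropped.
- h² = 0 is rejected (the noise variance formula divides by h²);
  h² = 1, and more generally V_G = 0, yields exactly zero noise.
- Phenotypes are not re-standardised: total phenotypic variance is
  whatever G and the calibrated noise produce. Users wanting unit
  variance can scale downstream.

## Effect-size distributions

`trait_model()` supports five univariate families — normal, fixed,
exponential, gamma and student-t — plus a multivariate normal for
pleiotropic traits. The univariate set matches common GWAS-simulator
practice; it is a deliberate package choice. Two details are worth
noting:

- Exponential and gamma distributions are positive, but effect sizes
  must admit both signs, so draws are multiplied by an equiprobable
  random sign by default (`random_sign = FALSE` disables this).
- The student-t draw is a standard t scaled to the requested variance
  (factor √(var·(df−2)/df)) and shifted by the mean; df ≤ 2 is
  rejected because the variance would be infinite.
- For pleiotropy, one joint draw per causal site is shared across the
  k traits; the frequency scaling is applied after the joint draw, per
  site, identically to every trait. Environmental noise is drawn
  independently per trait — correlation between traits enters only
  through effect sizes.

Covariance matrices must be symmetric positive semi-definite (checked
by eigenvalue, tolerance 1e-8 relative); draws use `MASS::mvrnorm`.

## Seeding and reproducibility

Every stochastic function takes an optional `seed`; `NULL` uses the
ambient RNG stream. A master seed is expanded into fixed-order
sub-seeds (site selection, allele choice, effect sizes, noise), so:

- `sim_phenotype()` equals `sim_trait()` → `genetic_values()` →
  `sim_env()` run manually with the derived sub-seeds;
- supplying causal sites explicitly does not perturb the allele and
  effect-size streams — the explicit path reproduces the random path
  exactly when handed the sites the random path would have drawn;
- genetic values accumulate as β·(carrier count) per site in
  ascending site order, one multiply and one add per site, so G is
  bit-reproducible and exactly equals the genotype-dosage sum
  Σ_s β_s g_{ind,s} an explicit genotype matrix would give.

The CSV outputs of `run_simulation()` are byte-identical across runs
with the same configuration and seed, whether driven from R or from the
command-line wrapper.

## The synthetic-ARG generator

`make_random_arg()` builds test ARGs entirely in code: independent
random coalescent topologies (exponential waiting times, uniform pair
merges) over shared sample nodes on `n_trees` equal genome segments of
100 bp each; sites placed uniformly; one mutation per site on a random
non-root branch; and, at a configurable rate, a second stacked mutation
on a descendant branch (half the time reverting to the ancestral state
— a back-mutation — with the parent-mutation link set) or, when the
first mutation hit a leaf branch, an independent mutation making the
site multiallelic. Sample nodes are paired into diploid individuals.

This generator deliberately exercises the hard structural cases —
recombination, stacked mutations, back-mutations, multiallelic sites,
odd ploidy — but it does not emulate realistic demography, linkage
patterns, mutation-rate variation or selection. Passing tests on these
fixtures therefore validates the *mechanics* of trait propagation and
calibration, not the population-genetic realism of any particular
input; for realistic inputs, ARGs from a coalescent simulator can be
loaded through `read_trees()`.

`make_example_arg()` freezes a minimal worked example: six sample
leaves `a`–`f` in three diploid individuals, one site (ancestral `A`)
with a mutation to `T` above internal node `i` and a back-mutation to
`A` above leaf `e`, so that every node below `i` except `e` carries the
causal allele and the `T` frequency is exactly 0.5. Only part of the
internal topology is forced by those constraints; the package fixes one
consistent shape — cherries (`a`,`b`), (`c`,`d`), (`e`,`f`) joined as
((`c`,`d`),(`e`,`f`)) under `i`, with (`a`,`b`) outside — and treats it
as canonical.

## Validation scales

The test suite checks, among other properties: exact agreement of the
traversal-based genetic values with a brute-force genotype-dosage
oracle on 100+ random ARGs (bit-for-bit); agreement of state resolution
with an independent per-node root-path walk; closed-form values of the
frequency scaling; moment checks of every effect-size distribution at
10⁵ draws; noise-variance calibration at 10⁵ individuals (within 4
standard errors); and recovery of requested heritabilities 0.3 and 0.8
to within ±0.03, averaged over 20 seeds, on a single-tree ARG of
10 000 diploid individuals with 50 causal sites drawn from 100
segregating sites. These sizes are the package's chosen validation
scale: large enough that the stochastic checks are sharp, small enough
that the whole suite runs in a few minutes on one CPU.

## Known limitations

- Only additive architectures: no dominance deviations, epistatic
  interactions, or liability-threshold binary traits.
- No shared-environment or covariate terms; noise is independent
  across individuals and traits.
- Causal-site placement is uniform over eligible sites (optionally
  frequency-weighted allele choice); no LD- or annotation-aware
  placement.
- The `.trees` reader shells out to the Python tskit library; without
  it, only the TSV dialect is available.
- ARG simulation and inference are out of scope: `argtrait` consumes
  ARGs, it does not produce them (beyond its own test fixtures).
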
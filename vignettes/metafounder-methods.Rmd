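---
title: "Genotype-derived metafounders: model, algebra and design choices"
author: "metafoundr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-derived metafounders: model, algebra and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafoundr)
```

## The genetic model

The numerator relationship matrix **A** treats pedigree founders as
unrelated and non-inbred: its base population has, conceptually, maximal
genetic diversity. A genomic relationship matrix **G** computed from
biallelic SNPs carries no such convention — its implicit base is set by the
allele frequencies used for centring. When the two are combined (as in
single-step genomic evaluation) they must refer to the same base, otherwise
systematic differences in level and dispersion between the matrices leak
into predictions as bias.

This package works with the convention that **G** is built at a fixed base
allele frequency of 0.5 at every locus (VanRaden's first method with
centring constant c = Σⱼ 2p_B q_B = m·H_B, H_B = 0.5). Under that
convention every diagonal element of **G** obeys the panmictic-index
identity

G_TT = 2 − H_T / H_B,

with H_T the animal's observed heterozygosity — that is, diagonals are
1 + F relative to a base of maximum heterozygosity. This identity is what
licenses the affine rescaling algebra below, and it is enforced to
machine precision in the test suite.

A real pedigree base is *not* at maximum heterozygosity. Its average
expected heterozygosity H_B relates to a scalar "self-relationship of the
base", γ = 2(1 − 2H_B) = 4(0.5 − H_B), and any relationship matrix can be
moved between bases by the elementwise affine map

A_X = (H_B / H_X)(A_B − 2) + 2,

whose fixed point is 2 (two copies of one genome stay two copies of one
genome under any change of base). The pivotal γ is estimable from data as

γ = (mean(G) − mean(A_g)) / (1 − mean(A_g)/2),

and rescaling A_g by its own pivotal γ makes the overall means of the two
matrices agree *exactly* — an algebraic closure, not an approximation,
which the acceptance checks verify to 1e-12.

With k strata the scalar γ generalises to the metafounder matrix

Γ = 8 (P′ − 0.5)(P − 0.5) / m,

computed from the m×k matrix of strata allele frequencies and referring to
the maximum-heterozygosity base. The chain implemented by
`build_A_gamma()` is: rescale Γ to the pedigree base,
Γ_B = (Γ − 2)/(2H_B) + 2; standardise to relationship form,
Γ_B* = (I − D_B) + Γ_B with D_B = diag(0.5 diag Γ_B); inject,
A_B^Γ = A_g + Q(Γ_B* − I)Q′; and rescale the result to the base of **G**,
A^Γ = 2H_B(A_B^Γ − 2) + 2. The injection step is an approximation (the
exact A^Γ requires tracing metafounder contributions through the whole
pedigree, which needs founder-level ancestry that genotype-derived strata
cannot supply); the package treats the chained expression as the defined
output. With k = 1 the chain collapses *exactly* to the single-γ
rescaling, a property tested to 1e-12 on random inputs.

## Estimating Q and P

`fit_admixture_lite()` maximises the binomial admixture likelihood by
block EM (frappe-style simultaneous updates of Q and P from the same
responsibilities). EM was chosen over quasi-Newton block relaxation for
transparency: every iteration provably does not decrease the
log-likelihood, and the trace is exposed and tested. Defaults: relative
log-likelihood tolerance 1e-6, at most 2000 iterations; hitting the cap
sets a `converged = FALSE` flag rather than erroring, because a
not-fully-converged fit is still a usable starting point in a sweep.
Allele frequencies are clipped to (1e-6, 1 − 1e-6) so no stratum can fix a
locus and zero out a likelihood term.

Initialisation is keyed to animal and marker *identifiers*, not row
positions: each animal's initial Dirichlet(1) ancestry row and each
marker's frequency perturbation derive from a hash of its id and the seed.
Consequently a permutation of the input rows yields the identical fit —
a property worth having in pipelines where genotype files are re-sorted —
and this invariance is tested.

Like any unsupervised mixture estimator, the likelihood is invariant to
relabelling the strata; tests that compare against generating truth align
labels by correlating frequency columns.

Ancestry rows for animals outside the fitted sample come from the
projection qᵢ′ = (P′P)⁻¹P′(0.5 zᵢ). Two row-level rules are applied:
negative components are clamped to zero *before* the sum check (the
clamping rule is this package's choice; proportions must be
non-negative to be interpretable), and rows summing above 1 are rescaled
proportionally to sum 1. With an intercept column in the design, the raw
intercept is reported per animal and animals above 0.1 are flagged — a
quality-control signal that k is too small. The intercept is reported as
estimated, without conversion to a "missing stratum contribution", since
that interpretation depends on assumptions about the missing stratum's
frequencies. Animals that were part of the strata fit keep their fitted
rows; the projection fills in only the rest. This makes the k = 1 case an
exact affine transform of A_g and mirrors the intended use of the
projection as an extension device.

`cv_error()` scores a choice of k by masking a fraction of genotype
entries, refitting, and predicting masked counts as 2 Σₗ qᵢₗ pⱼₗ. Because
the EM updates simply skip missing entries, masking requires no imputation
machinery.

## GLS strata frequencies

Frequencies estimated by the structure model are contaminated by family
structure: a large half-sib family is, to a mixture model, a stratum. The
Gengler-style GLS estimator

pⱼ = 0.5 (Q′A_g⁻¹Q)⁻¹ Q′A_g⁻¹ zⱼ

regresses genotypes on ancestry while whitening by the pedigree
relationship matrix, so that information already in A_g is not counted
again in Γ. A_g is Cholesky-factored once and reused across all markers.
Out-of-range estimates are truncated to [0, 1] and counted (the count is
part of the provenance record); truncation without re-estimation keeps the
Γ formula well defined and is the conservative option given that the
choice is not determined by theory. The `subset` argument allows
restricting estimation to a homogeneous set of animals (e.g. those with
most of their ancestry traceable to a fixed base period); computing such
ancestry fractions is left to the caller because it depends on information
(birth years, pedigree completeness) outside this package's scope.

## Half-sib thinning

`halfsib_sample()` reduces a genotyped set to at most one member per
paternal and per maternal half-sib group, removes animals whose two
parents are both genotyped, and force-keeps animals with both parents
unknown. Rules are applied in that order. Two readings of the published
rule set were open:

* "Keep all animals with unknown parents" is implemented as *both* parents
  unknown — the conservative reading; keeping every animal with a single
  missing parent would re-admit much of the sib structure the sampler
  exists to remove.
* "Remove its offspring" (for animals with both parents genotyped) is read
  as removing the offspring of genotyped pairs, i.e. the animal whose two
  parents are genotyped is itself redundant for strata estimation.

Within-group selection is by highest call rate (ties broken by pedigree
order, for determinism) or by a seeded uniform draw.

## The simulator

`simulate_population()` emulates the data situation the method is designed
for: k ancestral strata whose allele frequencies diverge by a
Balding–Nichols model (Beta-distributed around an ancestral frequency,
variance F_ST·p₀(1−p₀)) — chosen because it is the standard one-parameter
divergence model with closed-form moments that tests can use as oracles;
admixed founders with Dirichlet(α) ancestry; and discrete generations of
gene dropping in which a few sires each produce large paternal half-sib
families, the hallmark structure of dairy cattle. The "true" ancestry of a
non-founder is defined as the parental average — the expectation of
transmitted ancestry — which is what Q-recovery tests need.

Defaults (`sim_config()`): 3 strata, F_ST = 0.25, 2000 markers, 200
founders, α = 0.2 (founders mostly but not purely single-origin), 2
generations with 5 sires × 20 offspring. These are desk-scale stand-ins
for a realistic admixed breeding population: F_ST 0.2–0.3 corresponds to
well-differentiated cattle breeds, and α < 1 produces the mixture of
near-pure and admixed animals that makes strata detectable but not
trivial.

What the simulator does *not* model: linkage and LD (markers are
independent; the positional thinning utility is therefore exercised only
mechanically), selection, trait values, sex chromosomes, and genotyping
error. Passing tests consequently show correctness of the algebra and
estimators under the stated model, not robustness to LD-induced
overdispersion — the main reason published slopes fall below 1 on real
data.

All randomness flows through one seeded generator per call; RNG state of
the caller is saved and restored, and a fixed seed gives byte-identical
output.

## Numerical choices

* Pedigree relationship matrices use the dense tabular method (a_ii = 1 +
  0.5 a_sd; a_ij = 0.5(a_js + a_jd)); adequate to a few thousand animals,
  which is the intended desk scale.
* Missing genotypes are imputed at the centred base expectation (zero) in
  **G**, which leaves the centring constant and the diagonal identity
  intact for complete rows; marker QC should precede **G** anyway.
* Marker redundancy in QC means exact genotype-vector identity; the first
  occurrence is kept. Positional thinning keeps odd ranks (1st, 3rd, …)
  within each chromosome — "every other SNP" fixes the stride, not the
  phase, so the keep-first convention is declared for determinism.
* Element regression of A-variants on **G** uses all n² elements by
  default (`elements = "upper"` is available); the diagonal thereby enters
  once per animal rather than with double weight, and affine invariance of
  R² holds either way.
* PCA coordinates are eigenvector × eigenvalue (not √eigenvalue), matching
  the diagnostic convention this package targets; signs are fixed so the
  largest-magnitude loading of each component is positive.
* `select_k()` codifies an informal optimum: among k whose slope is below
  1 (+0.05 tolerance), take the maximal R²; ties by |b−1|, then
  |mean difference|, then smaller k. The slope cap guards against
  overdispersed A^Γ, which higher k tends to produce.

## Problem sizes in the tests

The stochastic test blocks run at: founders-only recovery n = 500 animals,
m = 5000 markers, k = 3, F_ST = 0.2 (10 GLS replicates, one EM fit);
k-sweep on 400 animals (200 founders + 2 generations of half-sib
families) × 2000 markers at k ∈ {1, 3}; Monte-Carlo gene-dropping
validation of the tabular method at 10⁵ replicates on a 12-animal
pedigree. These sizes were chosen as the smallest at which the stochastic
recovery bounds (Γ mean absolute deviation < 0.1, projection agreement
within 0.05) are comfortably stable across seeds.

## Limitations

* Q is defined for genotyped animals only; extending A^Γ across the whole
  pedigree would require extrapolating ancestry to non-genotyped
  ancestors, which the genotype-driven formulation deliberately avoids.
* The injected matrix is an approximation to the exact metafounder
  relationship matrix; no error bound is claimed for it beyond the exact
  k = 1 collapse.
* The EM estimator is desk-scale software: correct and monotone, but not
  competitive in speed with specialised block-relaxation solvers at
  hundreds of thousands of genotypes. For such data, fit externally and
  read the `.Q`/`.P` files.
* Choosing k remains a judgement: `select_k()` operationalises one
  defensible rule, and the sweep report is designed to be inspected, not
  only summarised.
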
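# shellevo

Eggshell stiffness and the comparative analysis of nest evolution.

Birds that build unsteady or enclosed nests — hanging (pensile) nests, nests
on reeds and vines, domed nests — expose their eggs to a higher risk of
egg-to-egg collision, and are predicted to lay stiffer-shelled eggs.
`shellevo` is for comparative biologists who want to test that kind of
prediction across a phylogeny. It provides both halves of the analysis:

1. **Egg mechanics.** An axisymmetric Kirchhoff–Love thin-shell
   finite-element solver computes the plate-compression stiffness *K*
   (N/m) of an egg from its breadth *A*, length *B*, shell thickness *t*
   and material (E, ν), and converts it to the dimensionless stiffness

   *C* = (*K*/*W*) · *A*²/*B*   (long axis; *W* = egg weight in N),

   which removes size and weight effects so stiffness can be compared from
   hummingbirds to ostriches. The solver is validated against the Reissner
   closed form for point-loaded spherical shells (two pole dimples in
   series) to within a few percent.

2. **Comparative methods.** Phylogenetic generalized least squares with
   maximum-likelihood Pagel's λ and AICc model selection over all category
   groupings; Pagel's dependent/independent correlated-evolution model for
   two binary traits (Felsenstein pruning in C++, MCMC with exponential
   priors, stepping-stone marginal likelihoods, Bayes factors on the
   2·Δlog scale); Brownian-motion ancestral state reconstruction (closed
   form and MCMC); and quantile-regression trends of *C* against node depth
   with bootstrap standard errors. A seeded synthetic-data module generates
   trees, trait histories, nest categories and egg geometries with known
   ground truth, so the whole pipeline is testable end to end.

## Worked example

Stiffness of a chicken-sized egg and its C number:

```r
library(shellevo)
prof <- build_profile(A = 0.0443, B = 0.0570, asymmetry = 0.12)  # metres
mat  <- shell_material(E = 3e10, nu = 0.3, thickness = 3.5e-4)
egg  <- egg_specimen(prof, mat, mass = 0.057)                    # kg
st   <- solve_axial_stiffness(egg)
st
#> <stiffness_result> K = 249855 N/m (long axis), 300 elements, converged (rel change 2.40e-05)
c_number(st$K, egg$weight, 0.0443, 0.0570)
#> <c_number> C = 15384.2 (log10 = 4.1871, long axis)
```

The C number of ~15,000 says this shell resists compression about
15,000 times its own weight-scale; published values for wild birds run from
roughly 5,000 to over 200,000.

A synthetic comparative study — simulate 200 species with a dome-nest
effect of +0.136 on log10 C, then fit the PGLS and run the grouping
selection:

```r
study <- simulate_study(n_tips = 200, seed = 1)
y <- setNames(study$traits$log10_C, study$traits$species)
f <- factor(study$traits$structure)
X <- model.matrix(~f); colnames(X) <- c("(Intercept)", paste0("structure:", levels(f)[-1]))
X <- cbind(X, clutch = study$traits$clutch); rownames(X) <- study$traits$species
fit_pgls(y, X, study$tree)
#> PGLS fit (n = 200, lambda = 0.403 [ML], logLik = 127.95, AICc = -241.32)
#>                    estimate         se       t         p
#> (Intercept)       4.2012789  0.0488351 86.0299 < 2.2e-16 ***
#> structure:cavity -0.0023319  0.0286713 -0.0813 0.9352615
#> structure:cup     0.0085357  0.0340766  0.2505 0.8024766
#> structure:dome    0.1468867  0.0419679  3.5000 0.0005766 ***
#> clutch            0.0060331  0.0063787  0.9458 0.3454097

grouping_selection(y, setNames(f, study$traits$species), study$tree,
                   covariates = cbind(clutch = setNames(study$traits$clutch,
                                                        study$traits$species)))
#> Best grouping (lowest AICc):
#>   { scrape/platform, cavity, cup }
#>   { dome }
#> Letters: scrape/platform=a  cavity=a  cup=a  dome=b
```

The dome effect is recovered (0.147 ± 0.042 against a simulated 0.136) and
the AICc grouping isolates dome nests from the other structures. At this
sample size the smaller cavity/cup effects (+0.066/+0.070 simulated) are
not separable from zero — as expected from their standard errors.

The full pipeline (simulate → stiffness → PGLS → correlated evolution →
ancestral states → trend) runs behind one call and writes a JSON manifest
with every seed and timing:

```r
run_pipeline(pipeline_config(out_dir = "out", n_tips = 120, seed = 42))
```

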
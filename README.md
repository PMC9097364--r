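# aviandiet

Quantitative diet and pedal-ecology inference for fossil birds from four
independent lines of evidence ("proxies"):

1. **Body mass** — a multivariate log10 regression on six skeletal
   measurements, with Youden-index mass cut-points between dietary guilds
   and mass-band exclusion rules (e.g. small-bodied taxa are unlikely
   vertebrate-eaters).
2. **Claw traditional morphometrics (TM)** — outer-arc curvature Oo and
   outer-arc length ratios ALo of the four pedal digits, separating ground
   birds from perching and raptorial taxa.
3. **Jaw mechanical advantage and functional indices** — AMA, PMA, OMA,
   AO, MCH, ACH measured on 2D lateral skull geometry.
4. **Finite-element jaw strength** — a plane-strain constant-strain-triangle
   solver for two-material (bone + rhamphotheca) jaw sections, summarised by
   mesh-weighted arithmetic mean (MWAM) strain and by the *intervals method*
   (percent model area per strain interval, treated as compositional data
   with log-ratio transforms).

The proxies are synthesised per taxon: each proxy can *exclude* diet
categories or *rank* them by discriminant posterior; the consensus permits
the complement of the union of exclusions and ranks the permitted set.

Phylogenetic structure is handled throughout: Brownian covariance from
time-scaled trees (with fossil grafting at stated stem/tip ages), Blomberg's
K and its multivariate generalisation (K = 1 under Brownian motion), and a
residual-randomisation permutation test of pairwise group means under the
phylogenetic covariance ("phylogenetic HSD").

A synthetic-data module generates trees, Brownian traits with guild
effects, claw arcs, jaw outlines and diet percentage tables with the
statistical structure the analysis assumes, so the entire pipeline runs and
is tested with no external data.

## Core statistics

For a trait vector `y` on a tree with Brownian covariance `C` (tip × tip
shared path lengths, Ma):

    K = [MSE0 / MSE] / [(tr(C) − N/(1'C⁻¹1)) / (N − 1)]

with `a = (1'C⁻¹1)⁻¹ 1'C⁻¹ y` the phylogenetic mean, `MSE0` the raw mean
squared deviation from `a` and `MSE` its `C⁻¹`-weighted form; permutation
p-values use (count + 1)/(nperm + 1) smoothing. The FE solver assembles CST
stiffness under plane strain (`D = E/((1+ν)(1−2ν)) [[1−ν,ν,0],[ν,1−ν,0],
[0,0,(1−2ν)/2]]`, bone E = 7000 MPa, rhamphotheca E = 3000 MPa, ν = 0.35),
applies a 6 N reference muscle load scaled by `F ∝ √area` so geometrically
similar models accrue identical strains, and reports the total maximum
in-plane principal strain in microstrain. Strain profiles are imputed
(truncated-lognormal replacement of compositional zeros) and ilr-transformed
before correlation-matrix PCA, LDA and DAPC; fossil specimens are always
projected as supplementary points and never influence the fit.

## Worked example

```r
library(aviandiet)

# body-mass proxy for a small-bodied fossil (log10 measurements, mm)
est <- enan_mass(list(HL = 1.462, bcL = 0.756, dHW = 0.398,
                      UL = 1.474, dUW = 0.334, TL = 1.505),
                 unit_to_g = 1000)
sprintf("mean %.0f g  [%.0f, %.0f]", est$mean, est$lower, est$upper)
#> "mean 79 g  [63, 98]"
mass_rule(est)
#> [1] "Piscivore"  "Scavenger"  "TetrapodHunter"
#> [4] "Folivore"   "FrugivoreH" "FrugivoreS"

# phylogenetic signal of a Brownian trait on a 32-tip, 94-Ma tree
tr <- simulate_tree(32, seed = 1)
y  <- simulate_bm_traits(tr, seed = 2)
blomberg_k(tr, y[, 1], nperm = 999, seed = 3)
#> K = 0.8223  (p = 0.001, 999 permutations)
```

The mass estimate of 79 g (interval 63–98 g) falls below every
carnivore/herbivore mass band, so vertivory (fish, carrion, tetrapods) and
folivory/frugivory are excluded, leaving invertivory, granivory,
nectarivory and generalist feeding as candidates for the other proxies to
narrow. The K near 1 with p at the permutation floor says the simulated
trait carries strong Brownian phylogenetic signal, as designed.

A full synthetic end-to-end run (jaw FE models → intervals → LDA → mass
rules → consensus) is available from the command line:

```sh
Rscript inst/exec/aviandiet run-all --seed 7 --out-dir out/
```

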
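# backbonediff

Generative modelling of protein backbone structures with **correlated
(polymer-structured) Gaussian diffusion**, for structural-bioinformatics and
protein-design researchers who want the generative machinery — prior,
sampler, denoiser and conditioning algebra — as composable, testable R
components at desk scale.

Protein backbones are not white-noise point clouds: they are chains whose
size obeys the globular scaling law *R*<sub>g</sub> ≈ *r*₀·*N*^ν.  The
package builds a Gaussian prior over CA coordinates that enforces both
constraints exactly — a centred random-walk (chain) covariance rescaled so
that E[*R*<sub>g</sub>²] = *r*₀²·*N*^(2ν) — and runs a variance-preserving
diffusion in the whitened space of that prior:

    x_t = α(t)·x₀ + σ(t)·ε_C,   ε_C ~ N(0, C),   α² + σ² = 1,

so that *t* = 1 yields random collapsed polymers rather than unstructured
noise.  Sampling reverses the process with a time-dependent denoiser
x̂₀(x_t, t), using the score identity s = C⁺(α·x̂₀ − x_t)/σ².  The package
provides:

* **Low-temperature sampling** — the score is rescaled by an inverse
  temperature λ with the injected noise variance divided by λ, plus ψ
  Langevin corrector sub-steps; on Gaussian data this provably samples
  N(μ, Σ/λ), giving an exact validation target.
* **A sub-quadratic graph denoiser** — a random geometry graph (chain
  edges + k-nearest neighbours + random long-range edges drawn ∝ d^(−p))
  with edge count linear in *N*; an SE(3)-equivariant message-passing
  network predicting inter-residue geometries and confidences; and a
  consensus solver that synthesizes global coordinates from those local
  predictions by monotone alternation of per-node Procrustes fits with a
  sparse least-squares (graph-Laplacian) update.  Trainable on one CPU in
  about a minute on synthetic backbones.
* **Composable conditioners** — exact point-group symmetry tessellation
  (Cn, Dn, T, O, I), substructure clamping (diffusion inpainting, exact at
  *t* = 0), harmonic distance restraints, entropic-optimal-transport shape
  guidance, and generic classifier guidance; hard constraints and soft
  energies mix freely in one stack.
* **Structural statistics** — radius of gyration, relative contact order,
  contact density, long-range contact fraction, CA-geometric secondary
  structure, Kabsch RMSD — plus PDB I/O, synthetic-structure generators and
  a small command-line layer (`inst/cli/backbonediff`).

## Worked example

```r
library(backbonediff)

prior <- polymer_prior(100, r0 = 2.0, nu = 0.4)
prior
#> <polymer_prior: N = 100, r0 = 2 A, nu = 0.4, centroid_sigma = 0 A, rank 99>
#>   E[Rg^2] = 159.243 A^2 (Rg law r0^2 N^(2 nu))

rg <- sapply(sample_prior(prior, 2000, seed = 1), radius_of_gyration)
sprintf("mean sampled Rg: %.2f A (law predicts %.2f A)", mean(rg), sqrt(prior_rg2(prior)))
#> "mean sampled Rg: 12.25 A (law predicts 12.62 A)"
```

The prior reproduces the scaling law it was built to enforce (the small gap
is Jensen's inequality: mean R<sub>g</sub> versus root-mean-square).
Structures and conditioners:

```r
helix <- make_ideal_helix(64)
round(structure_stats(helix), 3)
#>   n_residues radius_of_gyration contact_order contact_density
#> 1         64             27.805         0.055           1.891
#>   long_range_contact_fraction helix_fraction strand_fraction coil_fraction
#> 1                           0          0.969               0         0.031

apply_conditioner(make_symmetry_conditioner("C4", n_au = 64), helix)
#> <backbone_structure: 256 residues, 4 chains (A:64, B:64, C:64, D:64)>
```

The helix generator scores 97% helical under the package's CA-geometric
secondary-structure rules, and the C4 conditioner tessellates the 64-residue
unit into an exactly symmetric 4-chain complex.  Low-temperature sampling is
validated on Gaussian data, where the tempered law is known in closed form:

```r
sch <- diffusion_schedule()
p1  <- polymer_prior(1, centroid_sigma = 1)
toy <- gaussian_toy_denoiser(p1, sch, mean = c(1, -2, 0.5), cov = diag(3))
X <- do.call(rbind, sample_reverse_latent(
  p1, sch, toy,
  sampler_settings(inverse_temperature = 4, langevin_factor = 2,
                   n_steps = 200, seed = 7),
  n_samples = 5000))
apply(X, 2, var)
#> 0.247 0.248 0.254   # Sigma/lambda predicts 0.25
```

Training and sampling a structure model end to end (about a minute of CPU
for this toy corpus):

```r
corpus <- make_synthetic_set(100, c(40, 70), seed = 21)
fit <- train_denoiser(corpus, n_epochs = 25, seed = 5, hidden = 64)
fit                       # loss trajectory, architecture
residuals(fit, make_synthetic_set(5, c(40, 70), seed = 99), t = 0.2)
#> denoising RMSD per structure vs. the identity baseline
simulate(fit, nsim = 2, seed = 3, n_residues = 60)  # two sampled backbones
```

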
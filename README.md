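# dimerscope

Analysis of pH-dependent peptide dimerization from replica-exchange
conformational ensembles, built around the amyloid-β fragment
Aβ12–24 (VHHQKLVFFAEDV, Aβ numbering 12–24) studied as a capped
homodimer.

Early dimerization is a key event in amyloid formation, and its
thermodynamics depend strongly on pH through the protonation states of
His13/His14, Glu22 and Asp23. Replica-exchange molecular dynamics
(REMD) produces the equilibrium ensembles needed to study this, but the
analysis stack behind the published observables — exchange statistics
and replica walks, β-sheet registries, dihedral-PCA free-energy
landscapes, configurational entropy, potentials of mean force,
contact maps and solvation structure — is rarely available as tested,
reusable code. This package implements that stack in R, together with
synthetic-ensemble generators with known ground truth so every stage is
verifiable without running microsecond MD.

## What it computes

- **Protonation and ion accounting** — per-residue charge states as a
  function of pH (His/Glu/Asp/Lys bands), net charge, and neutralizing
  monovalent counterion counts; temperature ladders (explicit files or
  geometric fallback, the 64-rung 315.00–513.54 K ladder ships as a
  fixture).
- **Toy REMD engine** — Metropolis Monte Carlo walkers on analytic 1D
  potentials with the standard exchange criterion
  `p = min(1, exp[(βᵢ−βⱼ)(Eᵢ−Eⱼ)])`, alternating even/odd neighbour
  pairs; exchange logs, mean acceptance and dwell-fraction diagnostics.
- **Hydrogen bonds and secondary structure** — Kabsch–Sander energies
  `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol (bond if
  E < −0.5), DSSP-style assignment reduced to four classes (β-sheet,
  helix, bend/turn, coil), and the per-frame β-sheet length summed over
  both chains.
- **β-sheet registries** — inter-chain bridge pairs classified as
  parallel (index i−j) or antiparallel (i+j) in Aβ numbering, with
  block-averaged population histograms.
- **Landscapes and entropy** — dihedral PCA (PCA on the cos/sin
  embedding of φ/ψ), free-energy surfaces `V = −k_BT ln(N/N_max)`,
  watershed basin extraction with RMSD-clustered representatives, and
  quasiharmonic configurational entropy
  `S = k_B Σ_α [x_α/(e^{x_α}−1) − ln(1−e^{−x_α})]`,
  `x_α = ħω_α/k_BT`, `ω_α = (k_BT/λ_α)^{1/2}` from mass-weighted
  covariance eigenvalues λ_α.
- **Observables** — PMF over the inter-chain CHC (residues 17–21)
  centroid distance, side-chain contact probability maps, solute–water
  radial distribution functions, and block-averaged standard errors.
- **Synthetic generators** — ideal two-strand β-sheet builders with
  exact registries, angular-mixture dihedral ensembles, Boltzmann
  distance samplers, Gaussian coordinate trajectories with a prescribed
  covariance spectrum, and Poisson water shells.

## Worked example

Build a noisy antiparallel dimer with registry i+j = 39 (the register
seen in Aβ16–22 fibrils at low pH), then recover its structure
statistics:

```r
library(dimerscope)

spec <- dimer_fixture_spec("antiparallel", 39,
                           span_a = c(16, 22), span_b = c(17, 23),
                           noise_rms = 0.3)         # 0.3 A jitter
ens <- build_dimer_conformation(spec, seed = 1, n_models = 10)

ss <- assign_secondary_structure(ens)
beta_sheet_length(ss)$mean
#> [1] 16

registry_histogram(ens)$antiparallel
#>   index population stderr
#> 1    39          1      0

mean(interchain_chc_distance(ens))
#> [1] 0.5667287

assign_charge_states(2.9)
#> charge_model @ pH 2.90: HIS:1 GLU:0 ASP:0 LYS:1 other:0
counterion_count(peptide_spec(), assign_charge_states(2.9))
#> $species
#> [1] "anion"
#>
#> $count
#> [1] 6
```

All 10 frames keep the designed i+j = 39 register despite the jitter;
16 residues per frame sit in β-strands (the two bonded strands minus
DSSP's terminal-residue exclusions); the two central hydrophobic
clusters sit ~0.57 nm apart, as expected for a bonded sheet. At pH 2.9
the capped dimer carries +6 (two His and one Lys per chain) and is
neutralized by 6 anions (chloride).

A YAML-driven end-to-end run (`pipeline_run("run.yaml", "out/")`)
chains all stages and writes a JSON report plus TSV tables; a thin CLI
wrapper with verbs `toy-remd`, `synth`, `analyze` and `pipeline` is in
`inst/cli/dimerscope.R`.

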
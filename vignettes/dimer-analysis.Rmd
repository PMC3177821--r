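---
title: "Methods: analysing pH-dependent peptide dimerization ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing pH-dependent peptide dimerization ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerscope)
```

## Scope and model system

dimerscope analyses conformational ensembles of small peptide dimers of
the kind produced by temperature replica-exchange molecular dynamics
(REMD). Its reference system is the amyloid-β fragment Aβ12–24
(VHHQKLVFFAEDV, Aβ numbering 12–24), simulated as a homodimer with
N-terminal acetyl and C-terminal N-methylamide caps at three pH
conditions (2.9, 5.0, 8.4). The MD engine itself is out of scope: the
package consumes multi-model PDB ensembles or tabular series, and a toy
Monte Carlo replica-exchange engine stands in for the sampler where
exchange statistics themselves are the object of study.

## Protonation, charges, counterions

Fixed-charge simulations represent pH through discrete side-chain
protonation states. `assign_charge_states()` is piecewise constant over
three pH bands — below 4, Asp/Glu neutral and His +1; 4 to 6.5,
Asp/Glu −1 and His +1; above 6.5, His also neutral — with Lys +1
throughout. The band edges (4.0, 6.5) sit midway between the relevant
side-chain pKa values (Asp/Glu ≈ 3.9–4.1, His ≈ 6.0); only the three
point conditions are ever compared against reference numbers, so the
edges affect nothing checked elsewhere. Capped termini carry no charge;
for uncapped chains the zwitterionic pair (+1/−1) cancels in the net
charge anywhere well inside the terminal pKa values (2.29, 9.74), which
covers the 2.9–8.4 range handled here. Net charge is summed over chains
and neutralized by `|q|` monovalent counterions of the opposite sign
(chloride above, sodium below neutrality). For the capped Aβ12–24
dimer this yields +6/6 Cl⁻ at pH 2.9, +2/2 Cl⁻ at pH 5.0, −2/2 Na⁺ at
pH 8.4.

Temperature ladders are first-class inputs: the 64-temperature
315.00–513.54 K ladder used for this system ships as a plain-text
fixture (`ab_ladder64()`), and `geometric_ladder()` provides the
constant-ratio fallback. The ladder-prediction algorithm itself (which
requires system-composition heuristics) is deliberately not
reimplemented.

## Toy replica exchange

Within-replica propagation is Metropolis Monte Carlo with Gaussian
proposals rather than Langevin dynamics: the stationary distribution is
then exactly Boltzmann with no integrator error, which is what makes
the engine usable as a test oracle. The proposal width defaults to
`0.3·sqrt(kB·T)` nm per replica, which keeps within-replica acceptance
near 40% for the bundled potentials. Exchanges between neighbouring
temperature rungs are attempted every `exchange_interval` sweeps with
the standard criterion `min(1, exp[(βᵢ−βⱼ)(Eᵢ−Eⱼ)])`, alternating
deterministically between even and odd neighbour pairs (the alternation
convention is a free choice; alternating pairs keeps every rung
exchanging at the same rate). Throughout the package
kB = 0.008314462618 kJ mol⁻¹ K⁻¹. Randomness comes from R's default
generator; every run records its seed and is exactly reproducible from
it.

The bundled potentials (`harmonic`, `double_well`, `custom`) are
analytic stand-ins for the solvated system. The double well
`V(x) = barrier·((x−x₀)²/h² − 1)²` has its two minima at `x₀ ± h` and
barrier height `barrier` at `x₀`, so generator parameters translate
directly into the quantities the analysis should recover.

## Hydrogen bonds and secondary structure

Backbone hydrogen bonds use the Kabsch–Sander electrostatic model,
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with
distances in Å and a bond assigned when E < −0.5 kcal/mol; per donor
the two lowest-energy bonds are kept and donor–acceptor pairs are
screened at 9 Å Cα distance, as in DSSP. Missing amide hydrogens are
inferred geometrically — 1.0 Å from N, along the unit vector from the
preceding residue's carbonyl O to its C — which is the convention
reference DSSP implementations use, so PDB fixtures may omit hydrogens.
Chain-start residues have no amide H and never donate, and bridges are
evaluated only at residues with both chain neighbours present, again
matching reference DSSP behaviour (this is why two fully paired
7-residue strands score a β-sheet length of 10, not 14).

Assignment follows the DSSP rules — α/3₁₀/π helices from runs of
i→i+4/3/5 turns, β from parallel/antiparallel bridge patterns on the
hydrogen-bond graph, turns from isolated n-turns, bends from Cα kinks
above 70° — with raw letters retained and reduced to the four reporting
classes β-sheet, helix, bend/turn, coil (bend and turn are merged for
reporting; the letters remain available). The β-sheet length counts β
residues per frame over both chains, so values can exceed one chain's
strand length; the convergence series defaults to a cumulative running
mean (a windowed variant would also plateau but is noisier; the option
is exposed through `average`).

## β-sheet registries

A two-stranded inter-chain sheet is characterized by which residue
numbers pair: parallel ladders keep i−j constant, antiparallel ladders
keep i+j constant (Aβ numbering, so e.g. pairs (17,22),(18,21),(19,20)
are the antiparallel i+j = 39 register). `classify_frame_registry()`
reduces a frame's inter-chain DSSP bridges to one orientation and the
modal index; ties are broken toward the index supported by more
hydrogen-bond energy (the binning of genuinely mixed frames is not
standardized anywhere, so mixed-orientation frames are flagged and
reported separately rather than guessed). For homodimers the parallel
index is signed by input chain order (swapping labels negates i−j and
leaves i+j unchanged). Histogram populations are normalized by total
frame count, so parallel + antiparallel + no-bridge + flagged is
exactly 1, and errors come from 5-block averaging of the indicator
series. A `min_bridges` threshold (default 1) is exposed for analyses
that want to ignore single-bridge frames.

## Landscapes and entropy

Dihedral PCA avoids angle periodicity by embedding every angle as
(cos θ, sin θ) and running ordinary PCA on the 2M-dimensional result;
the eigenvalue sum equals the embedded total variance (checked to
1e-10 relative in the tests). Free-energy surfaces bin the first two
components on a 64×64 grid (padded 5% beyond the score range) and apply
`V = −kB·T·ln(N/N_max)`: the most populated bin is exactly zero and
empty bins are stored as NA, never as 0 — a sentinel matters because
`−kB·T·ln(0)` would otherwise silently flatten to a cap value.

Basins are extracted by watershed decomposition in order of increasing
V with persistence merging: at a saddle, a basin whose minimum lies
less than `min_depth` (default 1 kJ/mol) below the saddle is merged
into its deeper neighbour. The default reflects the resolution at
which distinct states are meaningfully reported on these landscapes
(statistical errors on them are of order 1 kJ/mol); without merging,
counting noise on a fine grid fragments each true basin into many
spurious ones. Basin frames are clustered by pairwise backbone RMSD
with the leader algorithm (cutoff 0.2 nm — no standard value exists;
0.2 nm backbone RMSD is a common same-conformation threshold for
peptides this size) and the medoid of the largest cluster is the
representative.

Quasiharmonic entropy builds the mass-weighted covariance of coordinate
fluctuations (optionally after least-squares superposition onto the
first frame to remove rigid-body motion), takes eigenvalues λ_α in
amu nm², assigns mode frequencies ω_α = sqrt(kB·T/λ_α) and sums the
quantum harmonic-oscillator entropy
S = kB Σ [x/(eˣ−1) − ln(1−e⁻ˣ)], x = ħω/(kB·T), with
ħ = 0.0635077993 kJ mol⁻¹ ps. GROMACS-style units (amu, nm, ps) make
1 amu nm² ps⁻² = 1 kJ/mol, so no conversion factors appear. Eigenvalues
below 1e-8 amu nm² are dropped: after superposition six near-zero
rigid-body modes remain numerically and a frozen mode's contribution
vanishes in the x→∞ limit anyway. Which atoms enter the covariance is
not standardized; the package takes whatever coordinates it is given
and the tests use backbone-heavy-atom and abstract mode ensembles.
The convergence diagnostic recomputes S on cumulative windows [0, t]
and declares a plateau when the tail slope of −T·S falls below
1 kJ/mol per unit window fraction.

## Observables

The PMF over the inter-chain distance uses the same direct-count
estimator as the 2D landscape, `V_i = −kB·T·ln(N_i/N_max)` on a 1D grid
(default bin 0.05 nm), with the same NA sentinel for empty bins; the 1D
and 2D paths are tested against each other on degenerate input. The
reaction coordinate is the distance between mass-weighted centroids of
the heavy atoms of the two central hydrophobic clusters (CHC, residues
17–21). Side-chain contact maps count frames where the minimum
side-chain heavy-atom distance falls below 0.45 nm (the common
side-chain contact convention; no value is standardized) and are
symmetrized for homodimers; glycine rows would be flagged (none occurs
in this sequence). Solute–water RDFs normalize pair counts by the
ideal-gas expectation at the global box density with minimum-image
distances (bin 0.01 nm), so uniform placement gives g ≈ 1 everywhere.
Statistical errors throughout use block averaging with 5 contiguous
blocks over the analysis window (default: the last 75% of a run),
mirroring the five-segment split of a 150-of-200 ns analysis window.

## Synthetic generators and what they do (not) emulate

Every generator is deterministic given its seed and logs its full
parameterization, and each has a matching analysis stage whose job is
to recover the generator's ground truth; these round-trips are the core
of the test suite.

The β-sheet builder constructs ideal periodic strands: starting from
the textbook antiparallel-strand torsions (φ, ψ) = (−139°, 135°), it
refines them (to about −138.3°, 135.7° with the package's bond
geometry) so the two-residue screw transform is a pure translation.
The refinement matters: with a non-zero residual twist per residue, no
single rigid placement of the partner strand can satisfy a
hydrogen-bond ladder of arbitrary length, whereas the zero-twist strand
makes the whole ladder exactly periodic. The partner chain is then
placed by rigid-body optimization of the registry's target
hydrogen-bond geometry (r_ON → 2.9 Å, r_OH → 1.9 Å) with a clash
penalty, from a small set of orientation starts; an index whose target
bonds cannot be realized (too little span overlap, or donors without
amide hydrogens) is rejected as unreachable rather than silently
approximated. Gaussian jitter of stated RMS per atom is added per
frame.

Angular ensembles draw i.i.d. frames from wrapped-normal mixtures
(any smooth unimodal angular family would do for recovery tests);
distances are drawn from exp(−V/kBT) by inverse-CDF on a 10⁴-point
grid (exactness over speed); Gaussian coordinate trajectories realize a
prescribed mass-weighted covariance spectrum mode by mode; water
oxygens are Poisson-placed as uniform background plus spherical shells
at stated density multiples.

None of these emulate real solvated-peptide physics: there are no
force-field energetics, no side chains beyond Cβ, no solvent structure
beyond designed shells, and frames are uncorrelated in time (except in
the toy REMD engine, whose correlations are those of the MC chain).
Passing round-trips therefore demonstrates that the analysis stack
recovers known structure and thermodynamics from data of the right
shape and scale — not that any particular MD result is correct.

## Problem sizes and numerical choices in the tests

The suite runs on one CPU in a few minutes: toy-REMD Boltzmann checks
use 2 replicas × 2×10⁴ sweeps with every-25th-sweep thinning before
goodness-of-fit (Metropolis chains are autocorrelated; testing the raw
chain would reject a correct sampler); entropy checks use 4×10⁴–5×10⁴
frames against closed forms with Wishart (λ√(2/n)) standard errors;
PMF recovery uses 2×10⁵ Boltzmann samples against a 12 kJ/mol
double-well barrier; the landscape check uses 10⁵ frames of a 90/10
angular mixture, whose free-energy split is kB·315·ln 9 ≈ 5.75 kJ/mol;
registry round-trips enumerate all 30 reachable indices for the default
spans; DSSP agreement is checked against an independent reference
implementation on a seven-fixture battery. Block-error calibration
compares the 5-block estimator with a bootstrap after averaging over
independent series, because a single 4-degrees-of-freedom error
estimate carries ~35% sampling noise of its own.

## Known limitations

- DSSP β-bulges are not implemented; ideal fixtures contain none, but
  irregular real sheets may lose an occasional bridge relative to full
  DSSP.
- The registry statistic assumes a two-chain system and reports one
  (orientation, index) per frame; intra-chain hairpins are out of
  scope for this 13-residue fragment.
- The builder's strands are rigid ideal geometry; it is a fixture
  generator, not a modelling tool.
- Configuration files are YAML; binary trajectory formats (XTC/TRR)
  are not parsed — convert to multi-model PDB upstream.
- Multi-temperature reweighting is not provided; analyses are
  single-temperature (default 315 K).
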
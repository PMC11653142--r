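# flexrestrain

Distance-restraint generation for coarse-grained protein flexibility
simulation, informed by AlphaFold per-residue confidence (pLDDT) scores.

Fast CA-level Monte Carlo samplers predict which parts of a protein move
and which stay put, but their accuracy hinges on the residue-pair distance
restraints that hold the input fold together. `flexrestrain` implements
nine restraint-generation modes — the three legacy secondary-structure
recipes (SS2 / SS1 / All), five pLDDT-based ones (min / max / mean /
pLDDT1 / pLDDT2), and a combined **category** scheme that classifies every
residue into one of four flexibility levels from secondary structure plus
confidence, then derives pair weights (0.0 / 0.5 / 1.0) from a category
matrix. It is aimed at structural bioinformaticians who want to generate,
inspect, perturb and benchmark such restraint sets on their own structures
or on fully synthetic fixtures.

## The model

Each restraint anchors a CA–CA distance at its value d₀ in the input
structure with a flat-bottom potential: zero energy within 1 Å of d₀,
then linear growth with per-side slopes

    E(d) = w · min_force · (d₀ − 1 − d)   for d < d₀ − 1
    E(d) = 0                              for |d − d₀| ≤ 1
    E(d) = w · max_force · (d − d₀ − 1)   for d > d₀ + 1

where w ∈ [0,1] is the mode-dependent pair weight. Defaults are the
optimized protocol values: pairs within 11.5 Å and at least 3 residues
apart in sequence, min_force 3.5, max_force 0.5, seed 7503. In category
mode a residue's base level (coil 0 < turn 1 < helix/sheet 2) is bumped up
at pLDDT ≥ 90, down below 50, and clamped to 0–3; a pair's weight is 0 if
either residue is fully flexible, 1 if both are rigid-ish (category ≥ 2),
0.5 otherwise.

Around the generator the package provides: PDB input with pLDDT read from
the B-factor column (or a TSV sidecar), DSSP 8→4 secondary-structure
collapse plus a geometric fallback, a clearly-labelled **stand-in**
off-lattice CA Metropolis sampler (not a CABS engine — see the vignette)
to exercise restraints end-to-end, Kabsch superposition, per-residue RMSF,
best-of-replicas Pearson scoring, paired t-tests, and synthetic fixture
generators with planted per-residue fluctuations.

## Worked example

```r
library(flexrestrain)

s <- helix_coil_helix(seed = 7503)    # packed 31-residue benchmark fixture
s
#> ProteinStructure 'helix-coil-helix-7503': 31 residues (31 with CA), chains: A
#>   pLDDT: complete; secondary structure: assigned

set <- generate_restraints(s)         # category mode, optimized defaults
set
#> RestraintSet: 121 restraints (mode category, max distance 11.5 A, gap >= 3)

traj <- run_sampler(s, set)           # stand-in CA Monte Carlo, seed 7503
pred <- compute_rmsf(traj)
pred
#> RMSFProfile: 31 residues, mean 2.125 A (range 1.163-5.200)

refs <- lapply(1:3, function(r) compute_rmsf(
  make_planted_trajectory(s, planted_sigma(s), n_frames = 300, seed = 7503 + r),
  superpose = FALSE))
best_replica_correlation(pred, refs)
#> EvalResult: best r = 0.725 over 3 replica(s) [0.724, 0.724, 0.725]
#>   mean RMSF: prediction 2.125 A, reference 0.616 A
```

The 121 restraints all live on the two high-confidence helices (including
inter-helix pairs that lock the fold); the pLDDT-40 loop and termini are
left free, fluctuate most in the sampled ensemble, and the predicted RMSF
profile correlates at r ≈ 0.73 with the planted-flexibility references —
while the unrestrained sampler on the same seeds stays well below that
(see the vignette for why shape, not amplitude, is the metric). Restraint
files are plain text, one `chain:res chain:res d0 weight` line per pair:

```
# mode=category max_distance=11.5 min_seq_gap=3 min_force=3.5 max_force=0.5 ...
A:5 A:8 5.054 1.000
A:5 A:9 6.203 1.000
...
```

The same pipeline is scriptable from a shell via the launcher in
`inst/exec/flexrestrain` (subcommands `fixtures`, `restraints`, `simulate`,
`evaluate`, `pipeline`; every one honors `--seed`, defaults to 7503, and
writes a JSON run manifest next to each output).

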
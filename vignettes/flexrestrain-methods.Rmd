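---
title: "Confidence-informed distance restraints for CA flexibility simulation"
author: "flexrestrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-informed distance restraints for CA flexibility simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexrestrain)
```

## The problem

Coarse-grained Monte Carlo samplers predict protein flexibility orders of
magnitude faster than all-atom molecular dynamics, but they rely on
residue-pair distance restraints to keep the input fold intact while letting
genuinely mobile regions move. Historically those restraints were derived
from secondary structure alone: restrain a pair when both residues sit in a
helix or strand (the classic "SS2" recipe), and leave everything else free.

AlphaFold's per-residue confidence score (pLDDT, 0-100, conventionally
stored in the B-factor column of predicted models) correlates strongly with
local rigidity: high-confidence regions tend to be static, low-confidence
loops and termini tend to move. `flexrestrain` implements a family of
restraint generators that exploit this signal, up to a combined
*category* scheme that merges secondary structure and pLDDT into a
four-level flexibility classification, and the evaluation machinery (RMSF
profiles, best-of-replicas Pearson correlation) needed to score the
resulting ensembles against reference data.

## The restraint model

Every restraint acts on the CA-CA distance $d_{ij}$ of a residue pair and
is anchored at the distance $d^0_{ij}$ observed in the input structure. The
potential is flat-bottomed and piecewise linear:

$$
E(d) =
\begin{cases}
 s_{\min}\,\bigl(d^0 - w - d\bigr) & d < d^0 - w\\
 0 & |d - d^0| \le w\\
 s_{\max}\,\bigl(d - d^0 - w\bigr) & d > d^0 + w
\end{cases}
$$

with flat half-width $w = 1\,\mathrm{\AA}$, and per-side slopes
$s_{\min} = \omega \cdot \texttt{min\_force}$,
$s_{\max} = \omega \cdot \texttt{max\_force}$, where $\omega \in [0,1]$ is
the pair's mode-dependent weight. The energy is zero at the input geometry,
non-negative everywhere, and continuous at both kinks, so restraints only
discourage non-ideal moves - they never pull the model toward a specific
alternative conformation. The defaults are the optimized protocol values:
`max_distance` 11.5 &#8491;, sequence gap 3, `min_force` 3.5 (compression is
penalized hard), `max_force` 0.5 (extension is penalized gently), giving
realistic flexibility without over-rigidification.

A note on the functional form: only the existence of a 1 &#8491; flat bottom
and of distinct per-side strengths is fixed by the protocol; the growth
outside the flat bottom is not prescribed. We use linear growth - the
simplest shape consistent with one strength parameter per side - and expose
a quadratic alternative behind `penalty_shape = "quadratic"`.

### Candidate pairs

A pair $(i, j)$ qualifies when both residues have CA coordinates, lie in the
same chain with sequence separation $j - i \ge$ `min_seq_gap` (the
inequality is inclusive: with the default gap 3, $j - i = 3$ qualifies), and
$d^0_{ij} \le$ `max_distance`. Inter-chain pairs are excluded by default
(`include_interchain = TRUE` enables them, with the gap rule applied only
within chains).

### The nine modes

Three legacy secondary-structure modes (weight 1 or pair dropped):
**ss2** (both residues helix/sheet), **ss1** (at least one), **all** (every
candidate pair). Five pLDDT modes: **min**, **max**, **mean** use the
pair's minimum / maximum / mean pLDDT divided by 100 as the weight, and
drop pairs whose weight falls below 0.5 (the comparison is strict, so a
weight of exactly 0.5 survives; whether the floor applies to *mean* is not
settled by the protocol description, so it is on by default and
configurable via `mean_floor`); **plddt1** and **plddt2** restrain at full
weight when at least one / both scores are strictly above 50.

The **category** mode combines both signals. Each residue gets a base level
from secondary structure - coil 0 (most flexible), turn 1, helix/sheet 2 -
which pLDDT then refines: scores at or above 90 raise the category by one,
scores below 50 lower it by one, clamped to 0..3 (3 = rigid). The exact
figure thresholds of the reference implementation are not printed in the
protocol text; 50 and 90 are the conventional AlphaFold "low" and "very
high" confidence boundaries, they reproduce the documented monotone
structure, and both cutoffs (plus the full 4x4 matrix below) are
configurable so alternative values can be dropped in verbatim. A symmetric
matrix then maps the two categories to a pair weight: 0.0 when either
residue is fully flexible (category 0), 1.0 when both are in the two most
rigid categories, 0.5 otherwise. Category assignment is monotone in pLDDT
by construction, which the test suite verifies over randomized sweeps.

### Subsampling

`subsample_restraints()` removes exactly `round(drop_fraction * N)`
restraints uniformly at random under a fixed seed (survivor order
preserved). Removing up to ~5 % of restraints should have minimal effect on
predictions; the operation exists to probe that robustness.

## The stand-in sampler

The package deliberately does **not** re-implement a lattice CABS-style
engine with a knowledge-based force field - that machinery is out of scope.
To exercise restraint sets end-to-end it ships a clearly-labelled stand-in:
an off-lattice CA-bead Metropolis Monte Carlo sampler whose energy has
exactly three terms: harmonic virtual bonds
($k_b = 20\,kT/\mathrm{\AA}^2$ around 3.8 &#8491;), a soft excluded-volume
repulsion ($k_{ev} = 5\,kT/\mathrm{\AA}^2$ below 3.5 &#8491;), and the
flat-bottom restraint term. Moves displace one bead at a time by an
isotropic Gaussian (sigma 0.35 &#8491;; terminal beads move like any other),
with Metropolis acceptance at fixed $kT = 1$ (energies are expressed in kT
units; there is no replica exchange). Snapshots are taken on the
attempted-move schedule, so the frame layout is independent of acceptance
history, and all randomness flows through one seed (default 7503):
fixed-seed runs are bit-reproducible, which the suite checks at the level
of serialized trajectory files. The C++ inner loop keeps an incrementally
updated energy that is cross-checked against an independent pure-R
recomputation (`pseudo_energy()`) at every snapshot to 1e-6.

Because the stand-in has no attractive non-bonded interactions, everything
that holds a fold together must come from the restraints. This is a feature
for testing (the restraint scheme's effect is unconfounded) and a known
limitation for realism (an unrestrained chain is a random coil, not a
molten globule). Run length and temperature have no protocol-prescribed
values; the defaults (200,000 attempted moves, snapshot every 1,000) are
the package's own choice, sized so that a full benchmark cohort runs in
seconds while unrestrained segments have time to decorrelate from the
input.

## Evaluation

`compute_rmsf()` implements the standard definition: after rigid-body
superposition of all frames (Kabsch fit - proper rotations only, reflection
corrected through the sign of the smallest singular value - first onto the
first frame, then one refinement pass onto the frame-average structure),
the RMSF of residue $i$ is the root mean squared displacement of its CA
from its average position. Superposition uses all CA atoms; the protocol
source does not specify the superposition or atom selection, so CA-only is
assumed throughout.

`best_replica_correlation()` scores a predicted profile against several
reference replicas and reports each Pearson correlation plus their maximum
- the convention used when multiple independent reference simulations of
the same protein exist. Pearson is the default ("correlation" unqualified
is read as product-moment, matching the original benchmarking practice);
Spearman is available behind `method = "spearman"`.
`paired_comparison()` wraps the two-sided paired t-test used for
method-level comparisons; when the paired differences have zero variance
the statistic is undefined and the implementation reports p = 1 for
identical samples and p = 0 for a constant non-zero shift (documented
convention, exercised in tests). p-values are reported, not used as
acceptance gates.

## Synthetic fixtures and what they do (and do not) show

`make_toy_structure()` builds CA traces from segment specifications: ideal
helix geometry (1.5 &#8491; rise, 2.3 &#8491; radius, 100&deg; twist) for
HELIX, 3.8 &#8491; extended steps for SHEET/COIL (coil directions get a
small seeded wobble so long coils are not collinear), and smooth 90&deg;
arcs for TURN; consecutive CA distances always land in [3.6, 4.0] &#8491;.
`make_planted_trajectory()` adds isotropic Gaussian noise with per-axis
standard deviation $\sigma_i/\sqrt{3}$, so the expected RMSF of residue $i$
is exactly $\sigma_i$ - a closed form the tests verify to within the
sampling error of 5,000-frame ensembles. By default planted flexibility
mirrors the common observation on globular proteins: low-confidence coil
and turn segments get sigma = 1.2 &#8491;, confident regular structure
0.3 &#8491;. Both levels are configurable, so counter-examples (a rigid
low-confidence helix, say) can be constructed deliberately.

The canonical benchmark fixture (`helix_coil_helix()`) is a 31-residue
*packed* fold: two 10-residue helices at pLDDT 95 joined by a 3-residue
loop that bends the chain through 180&deg;, so the helices sit antiparallel
about 10 &#8491; apart, flanked by 4-residue coil termini at pLDDT 40. The
packing is deliberate design: category-mode restraints then include
inter-helix pairs that lock the tertiary arrangement, as they do in a real
globular protein. An extended helix-coil-helix ribbon would leave the two
helices connected only through the loop, and with no attractive force
field they would flap freely about that hinge - a geometry no restraint
scheme is supposed to rescue, and one that says nothing about restraint
quality.

On a 10-fixture cohort of this shape, category-mode restraints plus the
stand-in sampler reach a median best-of-three-replicas Pearson r of about
0.73-0.77 against planted-flexibility references, versus about 0.14-0.40
for the unrestrained sampler on identical seeds (`scripts/acceptance.R`
recomputes both numbers). The predicted ensembles also fluctuate more in
absolute terms than the planted references (mean RMSF ~2.2 vs ~0.6
&#8491;) - profile *shape*, not amplitude, is what the correlation metric
rewards, and broader sampling at matched shape is expected from this kind
of coarse-grained exploration. What passing these tests shows is that the
category scheme transmits the confidence signal end-to-end: rigid where
confidence and structure agree, mobile where they do not. What it cannot
show is force-field realism - the fixtures are statistical, the sampler is
a stand-in, and no conclusion about agreement with real MD data on real
proteins should be drawn from them.

## Numerical choices and degenerate inputs

* Weights are compared to the min/max/mean floor before rounding, with
  strict `<` for dropping; pLDDT cutoffs in plddt1/plddt2 use strict `>`.
* Restraints are canonically ordered by (i, j); restraint files carry
  chain/residue identities plus d0 and weight to three decimals and
  round-trip exactly at that precision.
* The DSSP 8-to-4 collapse maps H/G/I to HELIX, E/B to SHEET, T/S to TURN,
  everything else to COIL. Mapping B (isolated bridge) to SHEET and S
  (bend) to TURN keeps the moderately-flexible class populated; the
  geometric fallback (`assign_ss_geometric()`, i/i+3 and i/i+4 distance
  signatures) detects only HELIX vs COIL, since strand pairing cannot be
  inferred from a lone CA trace, and collapses helix runs shorter than 3.
* Kabsch superposition rejects collinear or coincident references
  (rotation underdetermined); `pearson_r` rejects constant profiles rather
  than returning NaN.
* The sampler aborts with a divergence error if any coordinate strays more
  than 1,000 &#8491; from the initial centroid.
* Residues without CA atoms are carried through parsing but are never
  restrained and never appear in RMSF profiles.

## Known limitations

* With infinitely stiff restraint walls the ensemble still retains on the
  order of 1 &#8491; of collective per-residue play: the 1 &#8491; flat
  bottom leaves soft deformation modes (breathing, twisting) that keep
  every pair distance within tolerance while beads move coherently. Full
  rigidification below ~0.5 &#8491; RMSF would require shrinking the flat
  bottom itself (measured: mean restrained-residue RMSF 1.3 / 0.9 / 0.6 /
  0.5 &#8491; at half-widths 1.0 / 0.5 / 0.25 / 0.1), not raising the
  slopes - worth knowing when using strong forces to pin a region.
* Superposed RMSF carries a small least-squares fit bias (the 6 rigid-body
  degrees of freedom are absorbed from the signal), noticeable below ~30
  residues; the closed-form recovery tests therefore run with superposition
  off, and the superposition tests compare matched ensembles.
* Single-bead moves equilibrate local fluctuations quickly but global
  rearrangements slowly; trajectories are ensembles for RMSF, not kinetic
  pathways.
* altloc handling takes the first location; no mmCIF output; no side-chain
  or hydrogen chemistry anywhere.
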
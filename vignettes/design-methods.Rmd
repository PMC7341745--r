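---
title: "Physics-based fixed-backbone sequence design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-based fixed-backbone sequence design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdesign)
```

`cpdesign` implements the full computational arc of a physics-based protein
redesign study at desk scale: a fixed backbone is taken from a (synthetic or
experimental) structure, side chains are mutated and repacked by Metropolis
Monte Carlo under a molecular-mechanics energy with implicit solvent, the
lowest-folding-energy sequences are archived, a multi-stage empirical filter
cascade narrows the archive to a handful of candidates, and thermal-shift
analysis of differential scanning fluorimetry (DSF) curves evaluates whether
a candidate binds its peptide ligand. This vignette describes each model,
its assumptions, the parameters that matter, and the numerical and design
choices that were genuinely open.

## The folded-state energy

The folded state is scored with a pairwise molecular-mechanics energy plus
implicit solvation:

$$E_\text{fold} = E_\text{LJ} + E_\text{Coul} + \Delta G_\text{GB}
  + \sum_k \sigma_k A_k .$$

* **Lennard-Jones**: $4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ with
  Lorentz–Berthelot combining. 1–2 and 1–3 bonded pairs are excluded; 1–4
  pairs are scaled by 0.5 (LJ) and 1/1.2 (Coulomb), the conventional
  molecular-mechanics factors.
* **Coulomb**: $k\,q_iq_j/(\epsilon_P\,r_{ij})$ with
  $k = 332.0636$ kcal·Å/mol/e² and protein dielectric $\epsilon_P = 4$.
  Holding the backbone rigid ignores backbone relaxation; a protein
  dielectric of 4 is the standard way to absorb that missing flexibility
  into the electrostatics, and is a physically reasonable value for
  protein interiors.
* **Generalized Born**:
  $\Delta G_\text{GB} = -\tfrac{k}{2}\left(\tfrac1{\epsilon_P} -
  \tfrac1{\epsilon_W}\right) \sum_{ij} q_iq_j / f_\text{GB}(r_{ij}, B_i,
  B_j)$ with Still's interpolation
  $f_\text{GB} = \sqrt{r^2 + B_iB_j\,e^{-r^2/4B_iB_j}}$, solvent
  dielectric $\epsilon_W = 80$, and effective Born radii $B_i$ from
  Hawkins–Cramer–Truhlar (HCT) pairwise descreening with a global
  descreening scale of 0.8. The HCT integral is implemented analytically,
  including the engulfed-sphere case, and is validated in the test suite
  against numerical shell quadrature.
* **Nonpolar surface**: per-atom accessible areas weighted by atomic
  surface tensions (positive for C/S, negative for N/O, ±0.025/−0.06
  kcal/mol/Å², probe 1.4 Å).

### Two solvation regimes: frozen and fluctuating boundaries

The GB energy is many-body: every atom's Born radius depends on the whole
conformation, so mutating one side chain changes the solvation of all
others. The package implements both treatments used in the underlying
study:

* **FDB (fluctuating dielectric boundary)** recomputes every Born radius
  from the current state at every evaluation. This preserves the many-body
  physics but costs a full $O(N^2)$ descreening pass per Monte Carlo step,
  so `run_design()` restricts FDB runs to small systems by default.
* **NEA (native environment approximation)** descreens each atom by its
  own residue's current atoms plus the *native* atoms of every other
  residue. Radii assigned to a residue state are then independent of the
  rest of the query state. This is what makes the energy exactly
  decomposable as $E = E_\text{bb} + \sum_i e_i + \sum_{i<j} e_{ij}$ and
  lets `precompute_energy_matrix()` turn every subsequent energy change
  into a table lookup. On the native state the two regimes coincide
  exactly, which the tests assert at $10^{-6}$ kcal/mol.

### The surface term and pairwise decomposability

A numerical union surface area (Shrake–Rupley) is many-body: three or more
spheres can cover the same patch. A many-body surface term would break the
NEA pair matrix, whose exactness is the entire point of the approximation.
The energy therefore uses an analytic *pairwise* surface model: each atom's
area is its isolated accessible-sphere area minus 0.8 times the sum of
two-sphere overlap caps, unclamped. The scale factor compensates the double
counting of overlapping caps; at the packing densities of the toy systems
the model tracks the numerical union area closely. Shrake–Rupley areas
(`sasa()`, 960 deterministic golden-spiral points per atom, boundary ties
owned by the lower-index atom) are retained as an independent operation,
used for closed-form validation and as a cross-check oracle. Backbone–side
chain triple-overlap corrections are deliberately not modelled.

## The unfolded state and the design objective

The unfolded reference is an extended peptide: for each type X the central
residue of an Ala–X–Ala tripeptide at φ/ψ = −139°/+135° is evaluated with
FDB radii and minimized over the rotamer library
(`calibrate_extended_energies()`). Proline is the one exception: its ring
makes the generic extended φ sterically impossible, so its reference is
polyproline-II (−75°/+145°). On top of $E_\text{ext}$, per-type chemical
potentials $\mu_t$ (default 0) provide a composition control: adding
$\delta$ to $\mu_t$ changes the folding energy of any sequence by exactly
$-n_t\delta$ and nothing else, a linearity the tests assert. The design
objective is

$$\Delta E = E_\text{fold}(\text{state}) - \sum_i
  \left[E_\text{ext}(t_i) + \mu_{t_i}\right],$$

with lower values more favourable.

## Monte Carlo design

`run_design()` performs single-temperature Metropolis sampling at
kT = 0.6 kcal/mol by default, with an optional replica ladder
(nearest-neighbour swaps at a fixed interval). A proposal picks a
non-frozen position uniformly; at a mutable position it draws, with
probability 0.3, a new (type, rotamer) pair uniformly over all allowed
combinations, and otherwise re-draws a rotamer for the current type. Both
kernels are symmetric, so detailed balance holds with the plain Metropolis
rule; the move mix favours rotamer relaxation because at low kT most
mutation proposals clash and die. Every distinct sequence's best energy is
archived (default capacity 2,000), with first-seen order breaking energy
ties so runs are bit-reproducible from the seed. In NEA mode the energy
change of a move is an exact matrix lookup; the incremental total is
optionally re-derived from scratch at a configurable interval and must
agree to $10^{-6}$ kcal/mol.

Correctness of the sampler is established on an enumerable toy system
(`toy_design_system()`): two strand positions of a 10-residue hairpin, two
types with two rotamers each — 16 states whose exact Boltzmann weights are
computed by direct enumeration with the many-body-free evaluator. The toy's
types (Ser/Glu) were chosen because their rotamer pairs are nearly
degenerate on a strand, and the chemical potentials are set by the
documented balancing procedure so both types are populated; every state
then carries at least ~1% weight at kT = 0.6 and the χ² comparison is
well-posed. Because successive MC states are autocorrelated, visits are
recorded every 25th step before the χ² test — standard thinning, fixed in
advance. The packaged validation uses $10^6$ steps.

## The filtering cascade

`run_cascade()` applies seven stages in a fixed order: (1) keep the
`top_n` lowest folding energies; (2) exclude isoelectric points inside
[6.5, 8.5] (inclusive boundaries) — sequences near-neutral at
physiological pH aggregate and express poorly; (3) keep fold-recognition
records with match length strictly above the survivors' mean and
log₁₀E < −31; (4) keep sequences whose best-hit BLOSUM40 similarity to the
reference alignment is at or above the survivors' mean; (5) reject buried
cavities above 30 Å³; (6) require unsigned formal charge strictly below 6;
(7) allow at most 15 drastic mutations (BLOSUM62 score ≤ −2 against the
wild type, boundary inclusive). Stages 3–4 compute means over their input
set, so they are order-sensitive; stages 5–7 are independent per-sequence
predicates, and the tests verify both facts on synthetic data.

Numerical conventions: the isoelectric point is the bisection root (to
$10^{-4}$ pH) of the Henderson–Hasselbalch net charge with an
EMBOSS-style pKa set (C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1,
termini 8.6/3.6); a sequence whose charge never changes sign gets the
boundary pH with a warning. Formal charge is the integer composition count
(+1 K/R, −1 D/E, His and termini 0). Similarity is best-hit over the
reference set, with an optional position subset for core-only scoring; the
per-reference score vector is returned for histogramming. Cavities are
found by flood-filling the free space of a 1 Å occupancy grid (atom radius
+ 1.4 Å probe) from the bounding box; unreached free components are buried
voids. Fold recognition is consumed as an external score table — the
package generates synthetic tables but does not implement a fold
recognition algorithm.

`make_cascade_benchmark()` builds a 220-sequence archive in which every
sequence violates exactly one known stage (or none), with the separations
asserted at build time, so cascade attrition can be checked against planted
ground truth stage by stage.

## Thermal-shift analysis

`fit_t_half()` fits the Boltzmann sigmoid
$f(T) = f_\text{min} + (f_\text{max}-f_\text{min})/(1 + e^{(T_{1/2}-T)/s})$
by Levenberg–Marquardt least squares, initialized at the grid point of
maximum slope and retried over a small ladder of perturbed starts if the
first initialization is degenerate; falling transitions are handled by a
negative fitted amplitude. `thermal_shift()` takes replicate $T_{1/2}$
values (or raw curves) for apo and ligand-bound conditions and reports
$\delta T_{1/2} = \overline{T}_{1/2}^\text{holo} -
\overline{T}_{1/2}^\text{apo}$, positive for stabilization, with the
significance rule: the shift is significant when it exceeds the sum of the
two replicate standard deviations (sample sd, $n-1$; 0 for a single
replicate). Applied to published, rounded replicate summaries this rule
can sit exactly on the boundary for borderline ligands; such cases are a
rounding artefact of printed tables, and the package simply applies the
rule as stated.

## The synthetic-data generators and what they do not show

All inputs can be generated with seeded randomness: ideal-geometry
scaffolds (`make_scaffold()`: helix −57°/−47°, strand −139°/+135°, standard
bond lengths and angles, one to nine canonical-well rotamers per type),
ungapped reference alignments with a uniform substitution model
(`make_reference_msa()`), two-component fold-recognition score tables
(`make_fold_recognition_table()`), and sigmoidal melt curves with Gaussian
noise (`make_melt_curve()`). These fixtures exercise every code path with
exactly known ground truth, which is what the tests need. They do not
emulate real PDZ topology, side-chain packing in a native core,
evolutionary covariation in alignments, or instrument drift in DSF
signals — so passing tests demonstrate the correctness of the algorithms,
not the biological accuracy of the force field. The packaged parameter set
is likewise a reduced united-atom set (heavy atoms only, polar charges on
heavy atoms, per-element LJ/GB/tension parameters): the spec-level claims
of this package are structural and algorithmic, not force-field-accuracy
claims. The united-atom choice also keeps per-residue atom counts at the
conventional 4 + side-chain heavy atoms.

## Problem sizes and other fixed choices

The packaged validation workloads were sized for interactive use: toy
Boltzmann sampling uses a 16-state system at $10^6$ steps; matrix
reconstruction checks 50 random states of a 3-position problem; the
cascade benchmark holds 220 sequences; midpoint recovery uses 100
replicates at 2% noise. Other fixed conventions: coordinates are Å in the
PDB frame with author numbering preserved on read; insertion codes are
rejected; altloc A is preferred; His is modelled as a single neutral
tautomer; Born radii are capped at 50 Å to guard the deeply-buried limit;
equal-energy archive entries keep first-seen order; the hairpin generator
uses two canonical turn residues (−60°/−30°, −90°/0°) between strands.

## Known limitations

No backbone flexibility, loop rebuilding, or multi-chain design; no
Poisson–Boltzmann reference or salt dependence; a coarse
backbone-independent rotamer library; no dead-end elimination or exact
optimization; fold recognition and sequence databases are consumed as
tables, never computed; and no binding-affinity estimation beyond the DSF
significance rule.
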
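---
title: "Methods: structure-based prediction and fitting of hydrogen-exchange data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based prediction and fitting of hydrogen-exchange data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfkit)
```

## Scope and model

`pfkit` treats hydrogen/deuterium exchange (HDX) as a structure
interpretation problem: given a conformation (or ensemble) and a set of
experimental observations — per-residue protection factors from HDX-NMR,
or per-peptide deuterium-uptake curves from HDX-MS — how well does the
structure explain the data, and can a better-fitting conformation be
found by perturbing it?

The forward model is the phenomenological protection-factor expression

$$\ln P_i(C) = \beta^h N_i^h(C) + \beta^c N_i^c(C),$$

which attributes protection to two local determinants: hydrogen bonds
formed by the amide hydrogen ($N^h$) and packing density around it
($N^c$). It deliberately ignores electrostatics, solvent-accessible
surface area and segmental unfolding; those families of models have not
outperformed the bond-plus-packing picture in comparative evaluations,
and adding terms the data cannot constrain would be false precision.
Ensemble protection factors are averaged on the $\ln P$ scale,
$\ln P_i(S) = |S|^{-1}\sum_{C \in S} \ln P_i(C)$, never on $P$ itself.

### Counting conventions

* Hydrogen-bond acceptors are backbone carbonyl oxygens only (atom name
  `O`). The C-terminal carboxylate `OXT` is excluded: it is a terminus
  artifact, not a secondary-structure acceptor. Side-chain oxygens never
  count.
* Both counts measure Euclidean distance from the *amide hydrogen* of
  residue $i$; acceptors within 2.4 Å, heavy atoms within 6.5 Å.
* Residues $i-2 \ldots i+2$ (window inclusive of $i$ itself) are
  excluded from both counts, truncated at chain ends. This reflects that
  helix and sheet hydrogen bonds connect residues at least three apart;
  it also means a residue's own atoms never count as contacts.
* Distance comparisons use $\le$ at the cutoff. The boundary convention
  is arbitrary but must be fixed; ties at the cutoff are measure-zero
  for real coordinates.
* Several acceptors within the cutoff all count: $N^h$ is a count, not
  an indicator.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `beta_h` | 2 | — | ln *P* per hydrogen bond |
| `beta_c` | 0.35 | — | ln *P* per heavy-atom contact |
| `hbond_cutoff` | 2.4 | Å | H···O acceptor distance |
| `contact_cutoff` | 6.5 | Å | H···heavy-atom distance |
| `exclusion_window` | 2 | residues | half-width of excluded neighborhood |

The weights come from fits of the model to experimental exchange data
across multiple proteins (Best & Vendruscolo parameterization); the
cutoffs define the bond/contact counting and are part of the model, not
free knobs. All five are exposed in `model_params()` because sensitivity
analyses are legitimate, but results quoted by the package always use
the defaults.

## Structures and hydrogen placement

PDB parsing is delegated to `bio3d`; `pfkit` normalizes the records:
waters and unmappable hetero groups are dropped, common modified
residues (MSE, SEP, ...) map to their parent amino acid, alternate
locations resolve to the highest occupancy (ties toward altloc `A`),
and residues are renumbered 1..n with the author numbering retained for
joining experimental tables. Only the first protein chain is kept; the
counting rules are anchored to single-chain (monomeric) behavior, and
silently mixing chains would make the sequence-separation exclusion
ill-defined.

Crystal structures carry no hydrogens, so backbone amide hydrogens are
placed by ideal geometry: 1.01 Å from N, in the peptide plane defined
by C(i−1), N(i), CA(i), anti-parallel to the preceding C=O bond (the
trans amide). Experimentally determined hydrogen positions (e.g. NMR
models), when present in the file, are preserved rather than
re-idealized; whether that matches any particular upstream workflow is
unknowable from published methods, but discarding measured coordinates
by default seemed worse. Prolines and the chain N-terminus never
receive an amide hydrogen. Residues with missing backbone atoms are
flagged and simply omitted from the protection-factor map rather than
guessed at.

## Intrinsic rates and uptake kinetics

Unstructured-chain ("intrinsic") exchange rates are predicted with the
reference-parameter method of Bai, Milne, Mayne & Englander (1993):
poly-DL-alanine base rates for acid-, base- and water-catalyzed
exchange, per-residue nearest-neighbor inductive corrections (the
residue's own side chain acting on its own amide, the preceding side
chain acting from the left), terminal ammonium/carboxylate corrections,
and Arrhenius scaling with activation energies of 14/17/19 kcal/mol.
Conventions: time in minutes, rates in min⁻¹, the `pH` argument is read
as the pD of the labeling buffer, and the solvent is treated as 100%
D₂O with no forward-exchange correction. Asp, Glu and His use the
charged-form correction rows below their side-chain pKa and the neutral
rows above it — a step switch, not a titration-curve interpolation; at
the pH 7–8 conditions typical of labeling this affects His only, and
the package also accepts user-supplied per-residue rates, which bypass
the prediction entirely.

Residue uptake follows pseudo-first-order kinetics,
$d_i(t) = 1 - \exp(-(k^{int}_i/P_i)\,t)$. Peptide uptake is the
unweighted mean of $d_i(t)$ over the peptide's *exchangeable*
positions: the first two residues are always excluded (the N-terminal
amine loses its deuterium on digestion and drags the second amide with
it through back-exchange), prolines are excluded everywhere, and a
proline in position 1 or 2 does not free up an extra slot. Peptides
with no surviving position have undefined uptake and are reported as
such, not as zero.

## Goodness of fit and selection

For residue-level data the package reports per-residue
$|\ln P^{der}_i - \ln P^{obs}_i|$, its mean, and the squared Pearson
correlation between the two series. $R^2$ is reported together with the
correlation's sign: perfect anti-correlation also squares to 1, and
hiding that would be misleading. Zero-variance series make the
correlation undefined; the mean error is still computed. Observed
tables reported as $\log_{10} P$ are converted with
$\ln P = \log_{10} P \cdot \ln 10$ on input. Residues (or peptides)
present in only one series are dropped with a count, because real
datasets cover subsets of the chain.

For peptide-level data the error is
$\sum_{t \in T} |D^{der}_j(t) - D^{obs}_j(t)|$ on the experimental time
grid, averaged over peptides without length weighting.

`select_best()` scores every ensemble member through the full forward
pipeline and returns the minimizer; ties break toward the lowest index
(`best_index` is 1-based, following R convention). No claim is implied
that the winner represents the protein's state better than the
ensemble — only that it fits the HDX data better, which is the quantity
the search optimizes.

## Coarse-grained sampling

Conformations are perturbed in backbone internal coordinates: bond
lengths and angles fixed, ω = 180°, and moves add Gaussian noise
(`perturbation_sigma`, degrees) to the (φ, ψ) angles of one *fragment*
— a user- or automatically-defined set of residues chosen with
probability proportional to its weight. A dihedral change is applied as
a rigid rotation of everything downstream of the rotated bond, so the
input geometry (including a crystal structure's non-ideal bonds) is
preserved exactly outside the targeted angle. A separate
`rebuild_conformation()` reconstructs a backbone from a full dihedral
vector with ideal geometry, seeded at the template's first residue;
side chains ride rigidly in each residue's local backbone frame (no
rotamer repacking — a known accuracy limitation, since the contact
count is sensitive to side-chain positions).

Proposals are filtered by a soft-sphere clash score: over heavy-atom
pairs at sequence separation ≥ 2, $\sum \max(0,\ 3.0 - d)^2$ Å².
This is a deliberately simple surrogate for a molecular force field —
cheap, smooth near the boundary, and zero for clash-free structures —
with a pluggable interface (any scorer can replace it in
`sampler_config` workflows). The acceptance bound `energy_threshold` is
absolute; the default "auto" setting is 1.1× the start conformation's
score, and setting it to `Inf` disables filtering, which makes the
sampler deliberately more permissive than a physical simulation would
be.

Exploration grows a collection from the start structure by repeatedly
perturbing a uniformly chosen existing member and keeping proposals
under the threshold; it is fully deterministic given the seed. The
refinement loop (`iterate_refine`) runs one unbiased round, then
re-weights fragments by the current best conformation's per-residue fit
errors — the top quartile of fragment-mean discrepancy gets its weight
multiplied by `boost` (default 4), all weights renormalized — and
explores again from the current best, round $r$ seeded with
`seed + r − 1`. Defaults are 5 rounds and, for peptide data, peptide
errors are spread uniformly over the peptide's residues before fragment
aggregation. The boost factor and round count are package choices: the
approach only needs discrepant regions to be sampled *more*, not a
particular schedule.

## Synthetic data and what the tests show

The generators build poly-alanine chains (backbone + CB) with ideal
geometry at specified (φ, ψ): an α-helix at (−57, −47), an extended
chain at (180, 180), and random coils with φ ∈ (−180, −30),
ψ ∈ (−90, 180). `synthesize_observation()` runs the forward pipeline on
a known conformation and adds Gaussian noise (σ in ln *P* units for NMR
mode, uptake-fraction units for MS mode, MS values clipped to [0, 1]),
emitting the same file schema as real input. These fixtures emulate the
geometric features the model actually reads — helical i→i−4 hydrogen
bonds, packing-density contrasts, localized perturbations — but not
side-chain diversity, loop irregularity, multi-domain contacts, or
experimental noise structure. Tests passing on them validate the
arithmetic and the search machinery, not the biological accuracy of the
phenomenological model itself, whose known weaknesses (sensitivity to
small structural changes; no dynamics) are the reason conformational
sampling is needed in the first place.

Problem sizes used by the shipped test suite, chosen to exercise every
code path at fixture scale: counting equivalence against a brute-force
all-pairs oracle on 100 random 30-residue coils; selection and recovery
on 24-residue helices with 20 independent seeded refinement runs of 12
rounds × 20 conformations, against targets planted one sampler move
from the start (targets whose move changes no count carry no signal and
are redrawn). The recovery check asks the loop to beat the start
structure's fit error in at least 90% of runs.

## Numerical choices and degenerate inputs

* Determinism: every stochastic stage takes an explicit seed;
  `explore` seeds the RNG itself, `propose_move` consumes the current
  state. Identical configs give bit-identical ensembles.
* φ of residue 1 and ψ of residue n are undefined (an (N+1)-residue
  chain has 2N backbone degrees of freedom); moves skip them, and
  rebuilds use ψ = 180° only to place the terminal carbonyl oxygen.
* Packaged CI2/Im7 tables are checksum-verified on load and never
  recomputed; the CI2 numbering note (author residue 1 = residue 20 of
  the full protein) rides along as metadata.
* Empty intersections (no shared residues/peptides) are errors; partial
  overlap is not.
* CSV output is rounded to 6 significant digits for cross-platform
  byte-identity; JSON keeps full precision.

## Known limitations

Single-chain analysis only; no inter-chain acceptors or contacts in
multimers. Side chains are never repacked. The clash score is not an
energy; thresholds are not transferable between proteins. Intrinsic
rates use a step-function protonation model. EX1/correlated exchange
and isotope envelopes are out of scope; uptake is fractional, never in
Daltons.
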
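---
title: "Constraint-network rigidity analysis of channel ensembles: models and methods"
author: "cnaflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-network rigidity analysis of channel ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cnaflex)
```

# The scientific problem

Ion channels such as the hyperpolarization-activated, cyclic
nucleotide-modulated (HCN) family couple a transmembrane voltage sensor and a
cytosolic ligand-binding module (the C-linker/CNBD) to one pore gate. A
classic way to dissect that coupling is to loosen a mechanical joint — for
example the junction between the S6 gate helix and the A′-helix of the
C-linker — and ask which parts of the protein lose or gain conformational
stability, how the domains move relative to each other, and how the gating
and ligand-binding curves change. `cnaflex` provides the complete
computational side of such a study as a reusable, tested pipeline:

* **Rigidity analysis** of structure ensembles: constraint-network
  construction (covalent bonds, hydrogen bonds/salt bridges, hydrophobic
  tethers), rigid-cluster decomposition by a (6,6) body-bar pebble game,
  hydrogen-bond dilution, neighbor stability maps and per-residue chemical
  potential energies.
* **Ensemble geometry**: residue-wise RMSF after superposition, vertical
  inter-domain displacement \(d_z\), helix kink angles, residue-pair contact
  counts, and Kabsch–Sander secondary structure.
* **Electrophysiology/fluorometry fits**: the Boltzmann steady-state
  activation relation, single-exponential activation kinetics, the Hill
  binding curve, and the two-channel bound-fluorescence correction of
  confocal patch-clamp fluorometry (cPCF).
* **Synthetic-data generators** with known ground truth so that every stage
  of the pipeline can be exercised and validated without external inputs.

# The rigidity model

## Constraint networks

Each atom is a rigid body with six degrees of freedom. Interactions become
bars that remove relative degrees of freedom, with the multiplicities of the
FIRST/CNA body-bar convention:

| interaction | bars | notes |
|---|---|---|
| locked covalent bond | 6 | peptide bonds, sp2–sp2 bonds, ring bonds |
| rotatable covalent bond | 5 | leaves the torsion free |
| hydrogen bond / salt bridge | 5 | between donor and acceptor heavy atom |
| hydrophobic tether | 2 | weak, distance-based |

Two package conventions deserve mention because the underlying literature is
not explicit about them:

* **Bonds to terminal atoms are locked (6 bars).** A "rotation" about a bond
  axis through a degree-1 atom (an amide hydrogen, a carbonyl oxygen) moves
  nothing, so modelling it as rotatable would only inject spurious floppy
  modes.
* **Hydrophobic tethers are through-space only.** Carbon/sulfur pairs within
  the sum of their van der Waals radii (C 1.7 Å, S 1.8 Å) plus an offset
  \(D_\mathrm{cut} = 0.25\) Å become tethers, boundary inclusive, but pairs
  connected through three or fewer covalent bonds are excluded. Without this
  exclusion every backbone would carry C(i)–CA(i+1) tethers (2.4 Å apart)
  and be rigid at every cutoff, which would erase the hydrogen-bond dilution
  signal the whole method is built on.

Hydrogen bonds are detected from donor–H–acceptor triples that pass
geometric screens (H···A ≤ 2.6 Å, D–A ≤ 3.6 Å, 3.8 Å for salt bridges,
D–H···A ≥ 100°; all configurable via `hbondParams()`) and scored with the
Mayo-type energy

$$E_\mathrm{HB} = V_0\left[5\left(\frac{d_0}{d}\right)^{12} -
6\left(\frac{d_0}{d}\right)^{10}\right] F(\theta, \phi, \gamma),$$

with \(V_0 = 8\) kcal/mol, \(d_0 = 2.8\) Å, \(d\) the donor–acceptor
distance, and \(F\) a hybridisation-dependent angular factor built from the
standard cosine forms (sp3/sp3, sp3/sp2, sp2/sp3, sp2/sp2, the last with a
plane–plane term). At ideal geometry \(F = 1\) and \(E_\mathrm{HB} = -8\)
kcal/mol. Salt bridges between charged groups are scored with the radial
term alone at a longer equilibrium distance (\(d_0 = 3.287\) Å,
configurable) because the exact angular form used by the cited software
lineage is under-documented. Only attractive bonds (\(E_\mathrm{HB} < 0\))
enter the network. Hybridisation, donor/acceptor roles, covalent topology
and ring membership come from residue templates for the twenty amino acids;
hydrogens are attached to their heavy atom by distance, which is robust to
the many H-naming schemes of MD-derived PDB files.

## Pebble game and rigid clusters

`pebbleGame()` runs the (6,6) body-bar pebble game (Rcpp): each body holds
six pebbles; a bar copy is independent exactly when seven pebbles can be
gathered on its endpoints, and accepted copies are oriented away from the
paying endpoint so later searches can retrieve pebbles by path reversal.
Floppy modes are \(6n - 6c - r\) for \(n\) bodies, \(c\) connected
components and \(r\) independent bars. Rigid clusters are found by testing
bar-adjacent body pairs: a pair is co-rigid iff the seven-pebble gather
fails, and the reach set of a failed search provably carries \(6|D|-6\)
independent arcs and is united wholesale. Cluster labels are canonicalised
by lowest member index, making the decomposition independent of bar
insertion order. The test suite checks the decomposition (partition *and*
floppy-mode count) against an independent oracle — the numeric rank of
randomly realised generic rigidity matrices — on hundreds of random
networks.

## Dilution, stability maps, and per-residue energies

A dilution trajectory (`dilute()`) keeps only hydrogen bonds with
\(E_\mathrm{HB} \le E_\mathrm{cut}\) and decomposes the network at each
value of a strictly decreasing grid (default −0.1 to −6.0 kcal/mol in 0.1
steps, a conventional range; the grid is a parameter, not a fitted
quantity). Each in-contact residue pair (≥ 1 heavy-atom pair within 4.5 Å,
boundary inclusive) gets

$$rc_{ij} = \min\{E_\mathrm{cut} \mid \exists\, c \in C^{E_\mathrm{cut}}:
R_i \wedge R_j \in c\},$$

the deepest cutoff at which the two residues still share a rigid cluster. A
residue belongs to a cluster when at least one of its heavy atoms does (the
permissive standard). Pairs never co-rigid carry a sentinel one grid step
above the grid maximum (0.0 kcal/mol for the default grid), so the sums
below stay well defined; users preferring to drop such pairs can filter on
the sentinel. From the map, `stabilityProfile()` computes

$$E_{i} = \tfrac12 \sum_{j \ne i} rc_{ij}, \qquad
E_\mathrm{total} = \sum_{i < j} rc_{ij},$$

whose pair-halving identity \(\sum_i E_i = E_\mathrm{total}\) is asserted to
1e-9 in the tests. (The printed form of the total-sum equation in parts of
the CNA literature has an inner index that only makes sense as \(j > i\);
the identity above forces that reading.)

**Ensemble aggregation.** For an ensemble, `rc` is computed per snapshot and
averaged with the sentinel substituted in snapshots where a pair is out of
contact. This choice matters: averaging only over in-contact snapshots lets
transient contacts of a floppy region masquerade as stability, inverting the
expected sign of flexibility differences (we observed exactly this on the
synthetic hinge fixtures). Averaging per-snapshot profiles instead of maps
is also available (`aggregation = "profile"`).

**Differences.** `deltaStability()` computes
\(\Delta E_i = \bar E_i^\mathrm{ref} - \bar E_i^\mathrm{construct}\) with a
two-sided Welch unpaired t-test per residue across replicates (subunits ×
runs); negative values mean the construct is destabilised. Non-significant
residues (\(p \ge \alpha\), default \(\alpha = 0.05\)) are zeroed in the
reported map, raw values are retained, and no multiple-testing correction is
applied — both conventions follow common practice for these maps. Welch
rather than the equal-variance test is a deliberate default: the replicate
groups are small and there is no reason to assume equal variances.

# Geometry observables

* **RMSF** uses the Cα as the residue representative (atom-averaged
  heavy-atom RMSF is available) after least-squares superposition onto a
  reference selection; superposition itself is the Kabsch-type fit of
  `bio3d::fit.xyz` behind the `superpose()` surface. The default
  superposition atoms are backbone heavy atoms, configurable.
* **\(d_z\)** is the difference of mass-weighted heavy-atom z-centres
  between the four C-terminal residues of one subunit's S6 and the C-linker
  of the *declared* counter-clockwise preceding subunit; the subunit cycle is
  part of the `DomainAnnotation`, never inferred from geometry, and the
  convention assumes the pore axis is aligned with z (synthetic fixtures are
  built that way; experimental ensembles should be superposed onto an
  axis-aligned reference first).
* **Kink angle** between two helices is the angle between their N→C axis
  directions. The axis estimator is a principal component of the
  *smoothed* Cα trace: a running three-point average maps a helix onto a
  coaxial helix of ~0.23 the radius, removing almost all of the phase and
  finite-length bias that a raw PCA axis suffers (several degrees for
  two-turn segments) while averaging coordinate noise. Ranges of at least 12
  residues give sub-degree accuracy on ideal geometry; shorter ranges retain
  a bias of a degree or two that cancels in construct-versus-reference
  comparisons.
* **Contacts** between residue groups count residue pairs with any
  heavy-atom pair within 4.5 Å (inclusive), the same distance convention as
  the stability-map contact rule; the cutoff is a parameter.
* **Secondary structure** is a Kabsch–Sander assignment from backbone
  N–H···O=C electrostatic energies
  (\(E = 0.084 \cdot 332 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})\),
  bond below −0.5 kcal/mol), with turns at i→i+3/4/5 defining 3₁₀/α/π
  helices, bridges defining β structure, and precedence H > E > G > I > T.
  The amide hydrogen is reconstructed from the preceding peptide unit when
  absent. `ssContent()` counts H/G/I/E cells only — turns and bends are not
  secondary structure for this purpose.

# Parametric fits

Steady-state activation is fitted per recording with the Boltzmann relation

$$I/I_\mathrm{max} = \frac{I/I_{\mathrm{max,satV}}}
{1 + e^{z\delta F (V - V_{1/2})/RT}},$$

(voltages in mV; F = 96485 C/mol, R = 8.314 J mol⁻¹ K⁻¹, T = 295 K by
default — room temperature, configurable via `physicalConstants()`).
Per-recording fits are summarised as mean ± SEM (`fitBoltzmannSet()`), with
a pooled mode available. Activation time courses are fitted for
\(t \ge\) delay with the relaxation

$$I(t) = I_\infty - A e^{-(t-\mathrm{delay})/\tau},$$

which carries the same time constant as the decaying-exponential
parameterisation; activation currents grow toward a steady state, so the
relaxation sign convention is the physically meaningful one. The delay is
user-specifiable, with a default estimator (latest time before the absolute
slope first exceeds a tenth of its maximum). Binding curves are fitted with
the Hill relation \(F/F_\mathrm{max} = 1/(1 + (BC_{50}/x)^{H_b})\) on mean
data. All fits are Levenberg–Marquardt least squares with robust automatic
starting values (half-range voltage, \(z\delta = 4\), 1/e crossing,
interpolated half-maximum, \(H_b = 1.5\)); every returned fit satisfies its
midpoint identity (model at \(V_{1/2}\) or \(BC_{50}\) equals half the
plateau) to numerical precision.

For cPCF images, `extractBoundFluorescence()` scales the red (free-dye)
channel to the green channel inside the bath mask after offset correction
from a signal-free border, subtracts pixel-wise, and averages the remainder
over the patch mask; \(F_\mathrm{max}\) comes from user-designated
saturating reference frames, since the choice of those frames is an
experimental decision the package cannot make.

Summary statistics follow the two-level convention: time averages per
subunit, averaged per run, grand mean ± SEM across runs
(`grandMeanSem()`); significance via the Welch unpaired t-test
(`unpairedT()`), whose type-I error the acceptance suite verifies by
simulation.

# Synthetic data: what it emulates and what it does not

`generateHingedMultimer()` builds a C\(_n\)-symmetric multimer of ideal
poly-alanine two-helix chains (full backbone, Cβ, amide hydrogens placed in
the peptide plane) whose junction is a tunable hinge. Frames perturb the
backbone torsions of the two junction residues with wrapped-normal angles of
SD `hingeFlexibility`: this both bends the post-hinge helix and frays the
hydrogen bonds spanning the junction, which is how a floppy linker actually
destabilises its neighbourhood. An earlier rigid-body-bend design was
rejected because bending without fraying creates compensating contacts on
the compressed side and cancels the stability signal. A `plantedDzShift`
translates the post-hinge segment along z deterministically, so shift
recovery is tested with seed-paired ensembles where it is exact by
construction. Poly-alanine is deliberate: the analyses exercised by the
fixtures need backbone plus a minimal side chain, and the flexible-junction
phenotype is emulated by the hinge, not by sequence chemistry.

What the generator does **not** emulate: force-field energetics, solvent and
membrane, side-chain packing, correlated domain motions, and the slow
activation dynamics of a real channel. Passing the planted-effect tests
therefore demonstrates that the *analysis chain* recovers mobility,
displacement and destabilisation signals of known direction and magnitude
from structurally valid ensembles — not that it reproduces any particular
experimental system.

Trace generators (`generateActivationCurve()`, `generateActivationTrace()`,
`generateBindingCurve()`, `generateBindingImage()`) forward-simulate the fit
models with additive i.i.d. Gaussian noise (the simplest defensible noise
model, as recordings provide no better specification) and embed their ground
truth as an attribute. Every generator is a pure function of its arguments
including the seed.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as the package's own validation conditions: 4-chain, 20-residue
(two 10-residue helices) tetramers with 25 frames and two runs per construct
for planted-effect recovery; the default −0.1…−6.0 kcal/mol dilution grid;
200 random networks of up to 12 bodies for the pebble-game oracle; 500
Monte-Carlo replicates for fit recovery (noise SD 0.03 for activation
curves, 0.05 for binding curves); 10⁴ replicates for t-test calibration.
Hinge-flexibility contrasts use 2° (rigid reference) versus 15° (flexible
construct), and the planted displacement is 2.61 Å, mirroring the magnitude
scale of reported C-linker displacements in glycine-insertion studies.

Other numerical conventions: cluster ids are canonicalised by lowest atom
serial; the contact and tether boundaries are inclusive with a 1e-12
epsilon; the dilution exploits the monotone filtration only for bookkeeping
(each cutoff is decomposed independently, and a test asserts the partitions
refine); Welch degrees of freedom follow the Welch–Satterthwaite formula via
`stats::t.test`; zero-variance equal-mean groups return p = 1.

# Pipeline

`runComparison()` chains superposition → geometry observables → per-snapshot
networks → dilution → stability maps → ensemble profiles → per-residue
differences against the reference construct, and returns plain data.frames
(optionally written as TSV with a run manifest). Stage toggles exist and are
tested to produce identical numbers for the enabled stages. The pipeline is
exposed as R functions plus the YAML config reader (`readRunConfig()`)
rather than a shell executable: the package is an analysis library whose
users work in R, and a thin script wrapper would add a surface without
adding capability.

# Known limitations

* Covalent templates cover the twenty standard amino acids plus disulfides;
  ligands (e.g. cyclic nucleotides) and nucleic acids are not parameterised
  and nonstandard residues fail loudly rather than silently.
* The sp2/sp2 angular factor uses a plane–plane cosine; the exact
  salt-bridge angular treatment of the original software lineage is not
  published, so the radial-only variant with configurable \(d_0\) is used.
* The pebble game is exact for generic frameworks; pathological non-generic
  geometries (exactly parallel bars in a degenerate arrangement) are a
  measure-zero concern for molecular input and are not specially handled.
* rc values are grid-resolved: stability differences smaller than the grid
  step are invisible, and the sentinel convention adds a zero-energy
  contribution for never-co-rigid contacts that users can exclude.
* The 2G-style current-decay correction and any leak/capacitance
  compensation are out of scope; traces are assumed pre-processed.
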
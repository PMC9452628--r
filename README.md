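# cnaflex

Rigidity and gating analysis of ion-channel conformational ensembles.

`cnaflex` is an R package for asking a concrete structural question:
*when a mechanical joint of a channel protein — such as the junction
between the S6 gate helix and the A′-helix of the C-linker in an HCN
channel — is made flexible, which regions lose conformational stability,
how do the domains move, and how do the gating and ligand-binding curves
change?* It implements the full computational chain used in
glycine-insertion ("flexible linker") studies of channel gating:

* **Constraint-network rigidity analysis.** Structure snapshots become
  body-bar networks (locked/rotatable covalent bonds, Mayo-scored hydrogen
  bonds and salt bridges, distance-based hydrophobic tethers). A (6,6)
  body-bar **pebble game** (C++ core) decomposes each network into rigid
  clusters and floppy modes. Diluting hydrogen bonds in order of increasing
  strength along an energy-cutoff grid yields **neighbor stability maps**

  rc_ij = min{ E_cut : residues i and j still share a rigid cluster },

  over residue pairs in heavy-atom contact (≤ 4.5 Å), from which per-residue
  chemical potential energies E_i = ½ Σ_{j≠i} rc_ij, their total
  E_total = Σ_{i<j} rc_ij, and significance-tested reference-minus-construct
  difference maps ΔE_i (negative = destabilised) are computed.
* **Ensemble geometry.** Residue-wise RMSF after least-squares
  superposition, the vertical displacement d_z between the S6 C-terminus
  and the C-linker of the preceding subunit, helix kink angles, residue-pair
  contact counts, and Kabsch–Sander secondary structure.
* **Electrophysiology and fluorometry fits.** The Boltzmann steady-state
  activation relation I/I_max = I/I_max,satV / (1 + exp(zδF(V−V_1/2)/RT)),
  single-exponential activation kinetics I(t) = I_∞ − A·e^{−(t−delay)/τ},
  the Hill binding curve F/F_max = 1/(1 + (BC_50/x)^{H_b}), and the
  two-channel free-dye subtraction of confocal patch-clamp fluorometry.
* **Synthetic generators with ground truth.** C_n-symmetric hinged
  poly-alanine tetramers (tunable hinge flexibility, plantable displacement)
  and model-generated activation/binding data, so that every stage can be
  validated end to end with no external inputs.

The methods, conventions and their rationale are documented in the vignette
`vignettes/rigidity-methods.Rmd`.

## Worked example

Compare a rigid-junction tetramer ("0G") with a flexible-junction construct
("4G") over 25-frame ensembles:

```r
library(cnaflex)

wt  <- generateHingedMultimer(nChains = 4, helixLengths = c(10, 10),
                              hingeFlexibility = 2,  nFrames = 25,
                              seed = 101, construct = "0G")
mut <- generateHingedMultimer(nChains = 4, helixLengths = c(10, 10),
                              hingeFlexibility = 15, nFrames = 25,
                              seed = 201, construct = "4G")

report <- runComparison(list(wt$ensemble, mut$ensemble), wt$annotation,
                        reference = "0G")

subset(report$deltaStability, significant)[, c("resid", "dE", "p")]
#>  resid      dE            p
#>      8 -0.7870 0.0224812459
#>      9 -0.8145 0.0026395477
#>     10 -0.7945 0.0006899902
#>     11 -0.7235 0.0062532353
```

The hinge sits between residues 9 and 10 of each 20-residue chain: exactly
the hinge-adjacent residues come out significantly destabilised (negative
ΔE_i, in kcal/mol, Welch test across the four subunits × runs), while the
helix cores are unchanged — the flexible-linker phenotype the analysis is
designed to detect. The same report carries RMSF, d_z, kink-angle, contact
and secondary-structure tables.

Curve fitting works the same way on generated or measured tables:

```r
cur <- generateActivationCurve(vHalf = -119.6, zDelta = 3.5,
                               noiseSd = 0.02, seed = 7)
fitBoltzmann(cur$V, cur$relI)
#> Boltzmann fit: vHalf = -120.69 mV, zDelta = 3.363, plateau = 1.026

bc <- generateBindingCurve(bc50 = 0.51, hB = 1.4, noiseSd = 0.02, seed = 8)
fitHill(bc$x, bc$relF)
#> Hill fit: bc50 = 0.511 uM, hB = 1.41
```

With 2% measurement noise the fits recover the generating parameters
(V_1/2 = −119.6 mV; BC_50 = 0.51 µM, H_b = 1.4) to within a fraction of
their experimental uncertainty.

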
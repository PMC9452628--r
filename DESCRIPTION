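Package: cnaflex
Title: Rigidity and Gating Analysis of Ion-Channel Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constraint-network rigidity analysis of protein conformational
    ensembles and parametric analysis of ion-channel gating data. Builds
    covalent/hydrogen-bond/hydrophobic constraint networks from structure
    snapshots, decomposes them into rigid clusters with a (6,6) body-bar
    pebble game, performs hydrogen-bond dilution to obtain neighbor
    stability maps and per-residue chemical potential energies, computes
    ensemble geometry observables (RMSF, inter-domain displacement, helix
    kink angles, contacts, secondary structure), and fits Boltzmann, Hill
    and exponential models to electrophysiology and fluorometry data.
    Includes synthetic-data generators with known ground truth and an
    end-to-end construct-versus-wildtype comparison pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, bio3d, minpack.lm, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
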
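---
title: "Methods: coarse-grained poly-PR / karyopherin binding simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained poly-PR / karyopherin binding simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Arginine-rich dipeptide repeat proteins (poly-PR, translated from the
C9orf72 repeat expansion associated with ALS/FTD) bind members of the
β-karyopherin (Kapβ) family of nuclear transport receptors and interfere
with nucleocytoplasmic transport. `kapcg` implements a residue-scale
simulation-and-analysis pipeline to quantify that interaction: it builds
one-bead-per-amino-acid (1BPA) models of a structured receptor and a
disordered poly-PR chain, runs implicit-solvent Langevin dynamics at a
controlled monovalent salt concentration, and computes contact
statistics — the time-averaged number of contacts $C_t$, the binding
probability $P_b$, per-residue contact probabilities, contact counts
resolved over HEAT-repeat regions, and the overlap $N_\mathrm{shared}$
between poly-PR contact sites and the receptor's native binding sites.

## The model

Each residue is a single bead at the Cα position. Beads carry a formal
charge ($-1$ for D/E, $+1$ for R/K, 0 otherwise — histidine is treated
as neutral, matching the charge decoration convention of the underlying
1BPA family of models) and an aromatic flag (F/Y/W). A receptor's
tertiary structure is preserved by an elastic network: every pair of
structured beads separated by at least two positions in sequence and
closer than 1.4 nm is restrained by a stiff harmonic spring (8000
kJ mol⁻¹ nm⁻²) at its build-time distance. Residues missing from a
crystal structure are grown as disordered beads by a seeded
self-avoiding walk at the 0.38 nm virtual-bond spacing and excluded from
the network.

Nonbonded interactions depend on the chain roles:

* poly-PR ↔ receptor: Debye-screened electrostatics, a cation-π well
  between R/K and F/Y/W beads, and excluded volume;
* poly-PR ↔ poly-PR: screened electrostatics, a hydropathy-scaled
  hydrophobic well, and excluded volume;
* receptor internal: backbone, bending/torsion over disordered spans,
  the elastic network, and excluded volume (charges within one receptor
  are carried but their internal interactions are left to the network
  that already fixes the fold);
* receptor ↔ receptor (multi-copy runs): electrostatics plus excluded
  volume.

Screened electrostatics is the Debye–Hückel form
$U = f\,q_i q_j e^{-r/\lambda_D} / (\epsilon_r(r)\, r)$, truncated and
shifted to zero at the nonbonded cutoff. The screening length follows
the closed form
$\lambda_D = \sqrt{\epsilon_0\epsilon_r k_B T / (2 N_A e^2 I)}$
(≈ 0.975 nm at 100 mM, 300 K, $\epsilon_r = 80$; the 200 mM value is
smaller by $\sqrt2$). The permittivity is constant
($\epsilon_r = 80$) by default; an optional distance-dependent mode
$\epsilon_r(r) = \epsilon_r / (1 + (\epsilon_r - 1)e^{-r/\xi})$
interpolates from vacuum-like at contact to bulk water at long range.

The cation-π and hydrophobic terms are 12-6-style wells rescaled so
that, after cutoff shifting, the minimum is *exactly* the configured
depth at the configured range and the energy is *exactly* zero at the
cutoff (depth $d$, range $\sigma$:
$U = A[(\sigma/r)^{12} - 2(\sigma/r)^6] - A g(r_c)$ with
$A = d/(1+g(r_c))$). Excluded volume is the purely repulsive
Weeks–Chandler–Andersen form, zero at and beyond its diameter with a
continuous force. Bonded bending/torsion terms over disordered spans
are keyed by the residue-class patterning {G, P, other} of the central
bead(s).

### Parameters and defaults

The parameter tables of the published 1BPA force-field family are not
redistributed here; all
well depths, ranges and bonded-class constants are therefore
config-level defaults, shipped in one versioned parameter file
(`inst/extdata/ff_defaults.cfg`) and overridable through `ff_params()`.
The defaults (cation-π depth 3.5 kJ/mol at 0.5 nm; excluded-volume
2.5 kJ/mol at 0.6 nm diameter; hydrophobic depth 5 kJ/mol scaled by a
normalized Kyte–Doolittle hydropathy; backbone/elastic constants 8000
kJ mol⁻¹ nm⁻²; cutoff 2.0 nm with 0.3 nm Verlet skin, > 2 Debye lengths
at 100 mM) are physically conventional magnitudes for residue-scale
models — a few $k_BT$ for specific attractions, $\sim k_BT$ for soft
repulsion — chosen once and not fit to any observable. Conclusions
drawn from this package are therefore trend-level, not
parameter-level.

## Simulation protocol

Dynamics is NVT Langevin via the BAOAB splitting at 300 K with a
0.02 ps timestep and a 0.02 ps⁻¹ friction coefficient, in a periodic
cubic box (minimum-image convention). BAOAB was chosen for its accurate
configurational sampling at this timestep; the reference protocol of
record (GROMACS stochastic dynamics) is matched only at the level of
ensemble averages. The protocol of record runs ≥ 2.5 µs and analyzes
the last 2 µs; the package mirrors that with a default 20% equilibration
discard. The desk-scale default (2×10⁵ steps = 4 ns per run, box edge
4× the receptor's radius of gyration) is a deliberate scale-down used by
the test suite; the full protocol is a config change
(`sim_config(n_steps = 1.25e8)`). Velocities are Maxwell–Boltzmann;
chain placement and all noise are deterministic functions of the config
seed (the engine uses its own xoshiro256++ stream, so trajectories are
bit-reproducible across sessions).

Trajectories are stored as plain text (a JSON header plus per-frame
coordinate lines printed at 17 significant digits), which round-trips
doubles bit-for-bit; a PDB snapshot export is provided for external
viewers.

## Contact statistics

A pair contact is a (poly-PR bead, receptor bead) pair within 1 nm
(minimum image); a residue is in contact when it participates in at
least one pair. $C_t$ averages the per-frame pair count over production
frames, normalized by $N_{\mathrm{Kap}\beta} N_\mathrm{PR}$. $P_b$ is
the fraction of production frames in which *strictly more* than 10% of
the poly-PR residues are in contact. A receptor residue is a contact
site when its per-frame contact probability *strictly exceeds* 0.10.
Both strict inequalities follow the wording of the definitions. Whether
$C_t$ should count pairs or residues is ambiguous in the source
definition; the package defaults to pair counting and exposes
`mode = "residues"` as a switch. Uncertainties are half the standard
deviation over five equal contiguous production blocks (the exact
published block protocol is unknown; across replicate seeds the same
half-σ convention is applied to seed means). Classes of binding sites
with no known residues are reported as absent (`NA`), not as zero.

## The synthetic receptor

`generate_toy_solenoid()` emulates the statistical structure of an
importin without reproducing any real sequence: tandem HEAT repeats
(two antiparallel helices A and B joined by linkers) on a superhelical
arc, with B-helices forming the concave inner surface. (The source
figure captions are internally inconsistent about which helix class
faces inward; the main-text convention — B = inner — is adopted
throughout.) Negative charges are drawn bead-wise with probability
`inner_density` on inner-facing B-helix beads and `outer_density` on
outer-facing A-helix beads, classed by the sign of each bead's radial
offset from its helix axis; one mid-chain linker can be made fully
acidic (an H8-like insert). Toy binding sites mirror the native
layout: cargo and IBB classes on the inner surface, RanGTP on the
acidic linker plus inner residues, FG-Nup sites on the outer surface.
Default decoration (inner 0.6, outer 0.1, acidic linker on) gives an
NCPR around −0.15, inside the importin range.

What the toy does *not* capture: real sequence composition, the
specific electrostatic potential landscape of any receptor,
ring/U-shaped exportin geometries, and conformational flexibility of
the solenoid beyond elastic-network fluctuations. A green trend test on
the toy therefore establishes that the *pipeline* reproduces the
charge-, salt- and length-dependence mechanism, not that any particular
receptor's numbers are reproduced.

## Numerical choices

* Forces are validated against central finite differences of the total
  energy (relative error < 10⁻⁵ enforced in the acceptance suite).
* All pair terms are energy-continuous at their cutoffs; excluded
  volume is also force-continuous at its diameter.
* The Verlet list is rebuilt when any bead has moved more than half the
  skin since the last build.
* Overlapping beads (r < 10⁻⁴ nm) and non-finite coordinates abort with
  the pair/step identity rather than propagating NaNs.
* Disordered-region growth maintains the invariant that the remaining
  walk can always reach its anchor (reach ≥ distance), with a
  deterministic fallback, so construction cannot dead-end; resolved
  beads are never moved.
* Contact counting is exact brute force in compiled code (the bead
  counts make an $O(N_A N_B)$ scan per frame cheap); the engine's
  neighbor list is used only for dynamics and is itself checked against
  the brute-force route in the tests.

## Design decisions on open points

* **Ct counting mode** — pairs by default, residues as an option (both
  readings of the definition are defensible).
* **Uncertainty blocks** — five equal contiguous production blocks.
* **Kapβ–Kapβ inter-chain terms** — electrostatics + excluded volume
  (single-receptor runs make the choice moot).
* **Box edge** — 4× receptor gyration radius by default; not stated in
  the protocol of record.
* **Trajectory format** — plain text rather than binary, so archives
  are portable and diffable; lossless at 17 significant digits.
* **Configs** — flat `key: value` text files parsed by the package (no
  YAML dependency).

## Known limitations

Desk-scale runs are short enough that binding/unbinding statistics on
weakly charged receptors are noisy; trend assertions average over
seeds. The bonded bending/torsion constants are substitutes, so
poly-PR persistence length is only qualitatively right. No
phase-separation phenomena, free-energy estimates, or electrostatic
surface maps are in scope.
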
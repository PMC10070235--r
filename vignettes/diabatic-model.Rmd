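---
title: "A composite diabatic model for exciton and charge-transfer states in chromophore dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A composite diabatic model for exciton and charge-transfer states in chromophore dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabex)
```

## The physical problem

Closely stacked chlorophyll pairs — the Chla611–Chla612 dimer of the plant
light-harvesting complex LHCII is the canonical example — support two kinds
of low-lying excited states. *Locally excited* (LE) states are the Qy and Qx
bands of each pigment; *charge-transfer* (CT) states move an electron from
one pigment to the other (A⁺B⁻ or A⁻B⁺). CT states are optically dark, but
when a conformational change brings the pigments closer the CT energies
drop, the LE–CT couplings grow, and the lowest states become red-shifted
LE/CT mixtures — a mechanism implicated in the switch between
light-harvesting and quenched conformations.

`diabex` builds the six-state diabatic model that formalizes this picture.
The basis is the ordered set

\[
\{\,Q_{y1},\; Q_{x1},\; Q_{y2},\; Q_{x2},\; \mathrm{CT1},\; \mathrm{CT2}\,\},
\]

with CT1 = A⁺B⁻ (hole in the HOMO of fragment A, electron in the LUMO of
fragment B) and CT2 = A⁻B⁺. Diabatic states built from independent fragment
calculations are not mutually orthogonal, so adiabatic energies $E^{ad}$ and
coefficients $C^{ad}$ come from the generalized eigenvalue problem

\[
\mathbf{H}^{dia}\, C^{ad} = E^{ad}\, \mathbf{S}^{dia}\, C^{ad}.
\]

The ground state is excluded from the solved basis: its coupling to the LE
states vanishes by construction and its coupling to the CT states is checked
to be weak rather than carried along.

## Block structure and how each block is computed

`assemble_diabatic()` places the blocks as follows.

**LE diagonal (site energies).** Excitation energies of each pigment in
place. In toy mode they are frontier orbital gaps ($Q_y = \varepsilon_L -
\varepsilon_H$, $Q_x = \varepsilon_L - \varepsilon_{H'}$, with $H'$ the
HOMO−1); in file mode they are read from tabulated values. The container
enforces $Q_x \ge Q_y$ per pigment for toy provenance.

**LE/LE couplings.** Förster-type Coulomb couplings between the transition
densities of the two pigments, discretized as Mulliken transition charges:
$V = \sum_{s\in A, t\in B} q_s q_t / r_{st}$ (`coulomb_coupling()`). The
point-dipole approximation (`pda_coupling()`) is provided for comparison and
is reproduced to better than 1% once the separation exceeds about twenty
times the charge-set extent. Exchange–correlation and kinetic short-range
kernel contributions to this coupling require functional machinery that a
discrete-charge model cannot provide; the Coulomb term is the dominant
Förster contribution and is the one implemented. No empirical scaling of
transition dipoles is applied.

**CT diagonal.** Each CT energy is assembled as $E_{CT} = E_{ion} +
E_{int}$: Koopmans-style ionization energetics of the toy fragments
($E_{A^+}-E_A = -\varepsilon_{H_A}$, $E_{B^-}-E_B = +\varepsilon_{L_B}$)
plus the classical interaction energy of the two charged fragments,
referenced to the neutral pair. $E_{int}$ sums electron–electron
(two-centre Slater Coulomb integrals), electron–nucleus (exact 1s cloud
potentials) and nucleus–nucleus terms, and therefore carries the correct
$-1/R$ long-range limit for a ±1 pair. Non-additive functional terms have
no analogue in the toy densities; they are recorded as an explicit zero
component in the output rather than silently absorbed.

**GS–CT validity check.** The two-state Marcus machinery is available
separately: `marcus_coupling()` implements
$V_{01} = [H_{01} - S_{01}(H_{00}+H_{11})/2]/(1-S_{01}^2)$ and
`adiabatic_gap()` the corresponding two-state splitting. The diabatic
approximation $E_{CT} = H_{11}-H_{00}$ is flagged invalid when
$|V_{01}|/|H_{11}-H_{00}| > 0.1$. The threshold is a package choice: the
regime of interest is "coupling at least an order of magnitude below the
gap", and the flag is configurable.

**LE/CT couplings (generalized fragment-orbital scheme).** The interaction
Hamiltonian is approximated by the fixed supermolecular one-electron
Hamiltonian, diagonal in its orbital eigenbasis with energies
$\varepsilon_p$. LE and CT states are written as single hole/particle
excitations over *fragment* orbitals, expanded into supermolecular
orbitals through the overlap matrices

\[
S_{\rho_B,\pi_A} = \langle \phi_{\rho_B} | \phi_{\pi_A} \rangle, \qquad
S'_{p,\pi_A} = \langle \psi_p | \phi_{\pi_A} \rangle .
\]

With $i$ over occupied and $a$ over virtual supermolecular orbitals, the
fragment-A couplings are

\[
V^{Q_y^A,\mathrm{CT1}} = \sum_a \varepsilon_a S'_{a,L_A} S'_{a,L_B}
  - \sum_i \varepsilon_i S_{L_A,L_B} (S'_{i,H_A})^2,
\]
\[
V^{Q_x^A,\mathrm{CT1}} = -\sum_i \varepsilon_i S_{L_A,L_B}
  S'_{i,H'_A} S'_{i,H_A},
\]
\[
V^{Q_y^A,\mathrm{CT2}} = -\sum_i \varepsilon_i S'_{i,H_A} S'_{i,H_B}
  + \sum_a \varepsilon_a S_{H_A,H_B} (S'_{a,L_A})^2,
\]
\[
V^{Q_x^A,\mathrm{CT2}} = -\sum_i \varepsilon_i S'_{i,H'_A} S'_{i,H_B}
  + \sum_a \varepsilon_a S_{H'_A,H_B} (S'_{a,L_A})^2,
\]

and the fragment-B couplings follow by mechanical exchange of the A and B
roles — a stated assumption of this implementation. The first sums describe
electron transfer between the fragment LUMOs, the second hole transfer
among the HOMO/HOMO−1 sets. All eight (LE, CT) pairs are computed; the
$Q_x^A$/CT1-type entries carry only a HOMO/HOMO−1 cross term and vanish for
orthonormal fragment orbitals. `determinant_oracle()` keeps the brute-force
alternative alive: it expands both singly excited determinants in the
supermolecular determinant basis and contracts with the normal-ordered
diagonal Hamiltonian ($\varepsilon_a - \varepsilon_i$ per excitation). The
printed formulas are treated as normative; the oracle is used for
leading-order consistency only, and the test suite verifies that the
discrepancy between the two shrinks monotonically (empirically as the third
power of a global overlap scale) as the inter-fragment overlap is scaled
down.

**Zeros by construction.** The CT1–CT2 coupling and overlap are exactly
zero (opposite-polarity charge transfer is a two-electron process under a
one-electron Hamiltonian). LE–LE overlaps are unit-matrix entries. LE–CT
overlap entries default to single-determinant orbital-overlap products
(hole-orthogonality delta times electron overlap) when an overlap set is
supplied, and to zero otherwise; the scheme is a package assumption and can
be disabled by omitting the overlaps.

## The synthetic electronic-structure backend

No DFT engine is attached; instead `toy_fragment()` provides analytically
integrable fragments. Design choices:

* **1s Slater basis** (not Gaussian), so that orbital overlaps — and with
  them the LE/CT couplings — decay exponentially with distance, the regime
  the couplings are meant to probe. Equal-exponent overlap and Coulomb
  integrals have closed forms; unequal exponents fall back to radial
  quadrature (`stats::integrate`) in prolate-spheroidal or shell-averaged
  form.
* **Wolfsberg–Helmholz supermolecular Hamiltonian**: diagonal $\varepsilon_p$
  within a fragment, $\tfrac{1}{2}K(\varepsilon_p+\varepsilon_q)S_{pq}$
  between fragments, with $K = 1.75$ — the standard single-parameter choice
  that reproduces level splitting qualitatively. $K$ is an argument of
  `build_dimer()`.
* **Default fragment** (`toy_chla_fragment()`): four sites on a slightly
  irregular zigzag chain (spacing 2.6 bohr), $\zeta = 1.3\,$bohr⁻¹, four
  electrons, orbital energies $(-0.201, -0.191, -0.116, -0.040)$ hartree so
  the frontier gaps match the chlorophyll-a Q bands (Qy 2.04 eV, Qx
  2.31 eV). The deliberate irregularity keeps orbitals from being
  symmetry-pure, so transition dipoles and every inter-fragment overlap are
  generic rather than accidentally zero.
* **Spin** is integrated out: all orbitals are closed-shell spatial
  orbitals.
* **Units**: hartree and bohr internally; every file interface uses eV and
  Å (1 hartree = 27.211386 eV, 1 bohr = 0.52917721 Å). No mixed-unit files.

A known, accepted limitation of the Koopmans surrogate: because the toy
optical gap equals IP − EA, there is no exciton-binding offset, and at van
der Waals contact the unscreened $E_{int}$ can push toy CT energies below
the LE band — absolute toy CT energies are not chlorophyll-calibrated.
The trends the model is used for (monotone CT drop with distance,
degeneracy splitting by an asymmetric environment, $-1/R$ asymptotics) are
unaffected.

## Polarizable environment (DRF)

The environment is a set of sites with permanent charges $q_s$ and
isotropic polarizabilities $\alpha_s$. Induced dipoles solve
$\mu_s = \alpha_s [E^{perm}(s) + \sum_{t\neq s} T^{(2)}_{st}\mu_t]$ by a
direct $3N\times3N$ linear solve; a fixed-point iteration exists in the
test suite as an independent oracle. The potential at the quantum region is
$v^{el} + v^{pol}$ built from the order-0 and order-1 interaction tensors.
Short-range dipole interactions are Thole-damped by default with the
exponential form and damping parameter $a = 2.1304$ (the standard value
associated with Thole's atomic polarizability set; the damping expression
itself is a package choice since only the parameter set is standardized,
and `damping = "none"` is available). A response matrix that is not
positive definite raises a polarization-catastrophe error that suggests
damping.

Environment effects enter the model at first order: CT states are shifted
by the electrostatic-plus-induction energy of their state-difference
charges (re-solving the dipoles in the presence of those charges), LE
energies by `site_energy_shift()`, and LE/LE couplings by the response
correction $\Delta V = -\sum_s \mu^{ind}_s[\rho_A]\cdot T^{(1)} q^B$.
There is no self-consistency loop between environment dipoles and
orbitals — the toy backend has no SCF to couple to — and the response
correction is applied to LE/LE couplings only, matching the linear-response
construction; both simplifications are deliberate and documented here.

## Ensemble statistics and the red-shift analysis

Per-snapshot quantities live in long-format tables
(snapshot, label, value in eV, provenance). `ensemble_summary()` reports
means and **population** variances (divisor $n$); the convention is a
package choice and matters only for synthetic data. `gap_and_shift_report()`
derives the absolute CT1–CT2 gap per frame set and first-minus-last shifts,
rounding only at print time (2 decimals, the tabulated precision).

`simulate_dimer_ensemble()` is the synthetic-data generator. Its defaults
*are* the study conditions: 51 snapshots for the first frame set, 52 for
the last, with each of the six diabatic energies and eight coupling
magnitudes drawn independently from normal distributions at the tabulated
frame-set means and variances of the Chla611–Chla612 dimer
(`chla_dimer_reference()`), couplings truncated at zero. The generator
emulates snapshot-to-snapshot fluctuation about frame-set averages; it does
**not** model inter-label correlations, the geometric origin of the
fluctuations, or vibronic structure, so passing ensemble tests demonstrates
the statistical pipeline and the level-repulsion mechanism, not
force-field-level realism.

Solving the assembled model per snapshot and averaging the lowest adiabatic
state reproduces the mechanism under study: lowered CT energies plus
enlarged LE–CT and LE–LE couplings in the last frame set produce a strictly
negative shift of the lowest state (about −0.02 eV at the tabulated means,
with identity diabatic overlap and positive coupling signs — the tabulated
couplings are magnitudes, and the sign ambiguity is an intrinsic limitation
of assembling from absolute values; signed tables can be supplied).

## Numerical choices

* Generalized eigenproblems are reduced by Cholesky factorization of the
  metric; if the metric is numerically non-positive-definite the solver
  falls back to canonical orthogonalization, discarding metric eigenvalues
  below $10^{-8}$ with a warning. An independent $S^{-1/2}$ transformation
  solve serves as the test oracle.
* Orbital phases are fixed by making each orbital's largest-magnitude
  coefficient positive, so coupling signs are reproducible across runs;
  coupling magnitudes are invariant under any phase flip.
* Adiabatic states are ordered by energy; degeneracies are tie-broken by
  descending LE fraction, then label order, for deterministic output.
  Characters use the Löwdin partition $w = (S^{1/2}C)^2$ by default (a
  package choice — "character" has no unique definition); a Mulliken-style
  diagonal is available behind a flag, and the two coincide for an identity
  metric.
* `build_dimer()` rejects union bases whose metric has an eigenvalue below
  $10^{-6}$ or a condition number above $10^{10}$, naming the offending
  orbital pair.
* Quadratures use `stats::integrate` at relative tolerance $10^{-11}$ to
  $10^{-12}$; the two-centre Coulomb self-energy branch at $R=0$ returns
  the finite closed form ($5\zeta/8$ for equal exponents) with a distinct
  flag.

## Problem sizes

The shipped test suite and the acceptance script run toy dimers of 8 union
orbitals, separation scans of 5–10 bohr, DRF systems of up to 5 polarizable
sites, and synthetic ensembles of 51 + 52 snapshots — sizes chosen so the
whole analysis reruns in seconds while still exercising every formula at
non-trivial values.

## A worked example

```{r example}
d <- build_dimer(toy_chla_fragment("A"), toy_chla_fragment("B"),
                 displacement = c(1.0, 0.7, 6.5))
model <- assemble_diabatic(
  toy_site_energies(d),
  le_coupling = list(
    VQy = coulomb_coupling(make_transition_charges(d$fragA, c("H", "L")),
                           make_transition_charges(d$fragB, c("H", "L")),
                           unit = "eV"),
    VQx = coulomb_coupling(make_transition_charges(d$fragA, c("Hp", "L")),
                           make_transition_charges(d$fragB, c("Hp", "L")),
                           unit = "eV")),
  ct = ct_state_energies(d),
  lect = all_le_ct_couplings(d, unit = "eV"),
  overlaps = compute_overlaps(d))
solve_diabatic(model)
```

At this van der Waals separation the toy CT states come out *below* the LE
band — the Koopmans/unscreened-interaction limitation discussed above, not
a bug. Chlorophyll-like spectra are obtained by assembling from tabulated
energies instead, e.g.
`solve_snapshot(setNames(chla_dimer_reference()$mean_last, chla_dimer_reference()$label))`.

## Known limitations

* LE states are single orbital transitions; multi-configurational LE
  expansions are not composed into the couplings.
* The one-electron coupling Hamiltonian carries no two-electron integrals.
* Toy CT absolute energies are Koopmans surrogates (see above).
* Coupling signs from tabulated magnitudes default to positive.
* The environment model is first-order and isotropic; no anisotropic
  polarizabilities, no frequency dependence.
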
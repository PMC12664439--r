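---
title: "Modelling radiation-induced DNA double-strand breaks in lymphocyte nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiation-induced DNA double-strand breaks in lymphocyte nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphdsb)
```

## The model

When whole blood is irradiated ex vivo by a dissolved radionuclide, the
biological endpoint of interest is the number of DNA double-strand breaks
(DSBs) induced in lymphocyte nuclei per unit absorbed dose. Experimentally
this is measured as γ-H2AX/53BP1 radiation-induced foci per cell and per mGy;
at low doses a 1:1 correspondence between foci and DSBs is a reasonable
assumption. `lymphdsb` implements the computational counterpart as a chain of
two scales:

1. **Vial scale.** The 8 mL blood sample is a water cylinder (7.2 mm radius,
   49.12 mm height). Lymphocytes are 1000 equal spheres of 3.75 µm radius
   placed uniformly at random without overlap (`place_cells()`), a cell
   concentration of 125/mL. Each cell is a *cold source* — decays inside it
   are forbidden — and every particle crossing a cell surface is recorded as a
   phase-space row: name, kinetic energy, position, direction, weight, event
   and cell id (`phase_space()`).
2. **Cell scale.** Each per-cell phase space is translated so its cell centre
   is the origin (`translate_to_cell_origin()`), all cells are merged into a
   single total phase space (`merge_phase_spaces()`), and anti-neutrinos are
   stripped (`strip_antineutrinos()`). The nucleus is a water sphere of
   3.1 µm radius; only energy depositions inside it are scored.

The damage scorer works on point energy depositions inside the nucleus. Each
deposition is accepted as a strand break with probability

> SPointsProb × p(E),  p(E) = clamp((E − EMin) / (EMax − EMin), 0, 1)

with EMin = 5 eV, EMax = 37.5 eV. `SPointsProb` = 0.07 is the fraction of the
nucleus volume occupied by DNA, obtained geometrically: a DNA cylinder of
1.1 nm radius and 0.34 nm/bp × 6.4·10⁹ bp ≈ 2.18 m length has volume
≈ 8.3 µm³, against a nucleus volume of (4/3)π(3.1 µm)³ ≈ 124.8 µm³ — a ratio
of 0.066, i.e. 7% at integer rounding (`sensitive_fraction_geometric()`). A
molecular alternative divides the genome mass (6.41 pg) by the DNA density
(1.7 g/mL) for a DNA volume of ≈ 3.8 µm³ and a 3% fraction
(`sensitive_fraction_molecular()`); both are exposed and the unrounded
fractions are always returned.

Accepted breaks carry a strand label drawn Bernoulli(0.5) and are clustered
with DBSCAN (`cluster_breaks()`): neighbourhood radius eps = 3.4 nm (the span
of ~10 base pairs), MinPts = 2. A cluster with breaks on both strands is a
DSB — *simple* if it has exactly two members, *complex* with three or more; a
cluster confined to one strand is a complex SSB; noise points are isolated
SSBs (`classify_clusters()`). Scoring is strictly per primary particle:
breaks of different primaries are never clustered together.

Dosimetry closes the loop (`run_tally()` and friends): the mean energy per
nuclear transformation E/nt = ΣEᵢ/(N_cells·nt) with its history-by-history
standard error; the activity represented by nt simulated decays,
A = nt/(N1h·10⁶); the blood dose D = A·d_blood/8 mL; and finally
DSB·cell⁻¹·mGy⁻¹ = ΣDSB/(N_cells·D). For alpha emitters the package counts
alpha tracks per 100 cells per mGy, applies microscopy-motivated
detectability thresholds (length strictly > 0.75 µm *and* strictly > 7 DSBs),
and reports the linear DSB density as total DSB over total track length.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `spoints_prob` | 0.07 | — | geometric DNA volume fraction of the nucleus |
| `emin_damage_eV` | 5 | eV | below this no backbone damage |
| `emax_damage_eV` | 37.5 | eV | certain damage at and above |
| `eps_nm` | 3.4 | nm | 10 bp × 0.34 nm/bp; strict `<` |
| `min_pts` | 2 | — | a DSB needs two breaks |
| `strand_prob` | 0.5 | — | uniform strand assignment |
| cell / nucleus radius | 3.75 / 3.1 | µm | mean lymphocyte dimensions |
| vial | 7.2 × 49.12 | mm | 8 mL cylinder |

The printed source dimensions for the vial ("0.72 mm radius") give 0.08 mL,
not 8 mL; the package adopts 7.2 mm, which reproduces 8 mL to 0.005%, and
`vial_geometry()` verifies any declared nominal volume to 1%. The nucleus
mass computes to 1.248·10⁻¹³ kg at water density; a commonly quoted rounded
value is 1.24·10⁻¹³ kg, and the two agree within 1% — the package always
computes the mass from radius and density rather than hard-coding it.

## The synthetic track generator

Full track-structure transport is out of scope. To make the whole chain
executable and testable at desk scale, `generate_nucleus_exposure()` emulates
particle traversals: entry points uniform on the nucleus surface, inward
cosine-weighted directions (the isotropic-fluence entry law), straight chords
(no scattering), energy depositions as a 1-D Poisson process along the chord,
and i.i.d. deposition energies (lognormal, median 60 eV, sdlog 0.8). For
alphas the linear deposition density is an editable LET table (Bragg-peak
shape, ~226 keV/µm near 0.7 MeV, kinetic energies spanning 0.01–8.36 MeV)
divided by the mean deposition energy; electrons default to a sparse constant
0.5/µm. The alpha track length inside the nucleus is identified with the
chord, which is also the generator's main fidelity limit: real low-energy
alphas and especially electrons scatter, produce delta rays, and have
energy-loss straggling, none of which is modelled.

Consequently, passing tests demonstrate that the *scoring machinery* is
correct (clustering equals a brute-force oracle, acceptance rates match their
Bernoulli model, bookkeeping conserves counts, conversions invert cleanly) —
they do not validate the placeholder deposition physics against real tracks.
The one physics-flavoured check is deliberately broad: the synthetic
high-LET alpha model must land in a 3–30 DSB/µm order-of-magnitude band.
Quantitative use requires replacing the LET table and spectra with
transport-code inputs, or scoring externally generated deposition lists via
`read_exposure()`.

One bookkeeping consequence deserves emphasis: in the synthetic chain every
primary traverses the nucleus, whereas in a real vial only a small fraction
of decays send a particle through any of the 1000 cells. With the default
convention nt = number of synthetic primaries, the simulated activity and
blood dose are therefore far smaller than in a matching experiment, and the
resulting DSB·cell⁻¹·mGy⁻¹ is correspondingly inflated. It remains exactly
proportional to the conversion chain (halving the dose doubles it), so it
exercises the dosimetry code, but only the per-micrometre DSB density of
alpha tracks is physically interpretable from synthetic runs. Scoring a real
total phase space with its true nt restores the experimental scale.

## Numerical and design choices

* **Strict eps.** "Separated by less than 10 bp" is a strict inequality:
  breaks exactly 3.4 nm apart do not join. With MinPts = 2 every non-noise
  point is a core point, so the DBSCAN partition equals the connected
  components of the proximity graph and is independent of input order;
  clusters are reported sorted by their minimal member coordinate.
* **One combined Bernoulli draw** with probability `spoints_prob · p(E)`
  replaces two sequential draws; the acceptance law is identical and the
  random stream half as long. The ramp is implemented as the clamped linear
  text description (0 at ≤5 eV, 1 at ≥37.5 eV).
* **Per-track clustering.** Damage tuples are per primary particle; breaks
  from different primaries, however close, are never merged. Inter-track
  proximity damage is explicitly not modelled.
* **History-by-history uncertainty** uses N = nt with zero-deposit events
  included as explicit zeros, equivalent to `sd(E)/sqrt(N)/N_cells`.
* **N1h** (transformations per Bq in one hour) is the closed-form decay
  integral (1 − e^(−λ·3600 s))/λ, monotone in half-life and bounded by 3600;
  a non-decay-corrected mode (plain 3600·A) is available for comparison with
  conventions that ignore decay during the hour.
* **d_lymph convention.** The nucleus dose coefficient is defined so that
  D_nucleus = A[MBq]·d_lymph/volume, the mirror image of the whole-blood
  relation, which makes d_lymph directly comparable to d_blood. Energies are
  keV internally, converted at 1 keV = 1.602176634·10⁻¹⁶ J.
* **Seeding.** Every stochastic function takes an explicit seed; the pipeline
  refuses a configuration without one. Per-track seeds derive from the master
  seed plus the track index, and replicate runs use seed, seed+1, …, with the
  replicate spread reported as a sample standard deviation over k runs
  (default 5).
* **Degenerate inputs** are first-class: empty phase spaces (e.g. after
  stripping a pure anti-neutrino source), zero-density tracks (chord still
  reported), tracks with no depositions (all-zero summaries), and zero
  accepted breaks all flow through the chain and yield zero dose and damage.
* **Containers.** Phase spaces, depositions, placements and summaries are
  tibbles and round-trip through plain CSV with full double precision;
  configuration is YAML. The package cannot read transport-code binary
  output; a converter to the CSV schema is the user's responsibility.

## Problem sizes

The bundled tests and the reproduction script run the chain at desk scale,
chosen so the statistical assertions have adequate power while the whole
suite stays lightweight: 1000-cell placements (20 seeds) for the packing
invariants, 200 random break fixtures of up to 1000 points for the
clustering-oracle equivalence, 100-seed replications for acceptance-rate
checks, and synthetic exposures of 150–200 alpha primaries (~10⁶ depositions)
for the end-to-end chain. All fixtures are generated in code from fixed
seeds.

## Known limitations

No indirect (radical-mediated) damage, no 3-D chromatin geometry, no repair
kinetics, no microscopy point-spread simulation, no cell-size distribution
(all lymphocytes share the mean radius), straight-chord tracks without
delta rays, and placeholder deposition spectra. The dose coefficient
`d_blood` is a required external input — it comes from a macroscopic
transport calculation or measurement and is not reproduced here.
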
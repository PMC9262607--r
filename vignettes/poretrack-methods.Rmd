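---
title: "PoreTrack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PoreTrack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoreTrack)
```

## The problem

Superfamily-2 helicases such as the XPD subunit of TFIIH verify bulky
DNA lesions during nucleotide excision repair by stalling: undamaged
single-stranded DNA threads through the entry pore formed by the FeS,
Arch and ATPase-lobe-1 domains, while a bulky adduct (for example a
tandem pyrimidine-pyrimidone UV photoproduct) is gripped near the pore
and cannot pass. Microsecond molecular-dynamics trajectories of such
systems are interrogated with a recurring set of observables:

* **per-nucleotide displacement after pore superposition** — every
  frame is superposed onto a reference on the pore Cα atoms (Kabsch,
  proper rotations only), then the displacement of the nucleotide's
  backbone phosphorus from its reference position and the heavy-atom
  RMSD of the whole nucleotide are recorded. A mean P displacement on
  the order of the B-form adjacent phosphate spacing (~7 Å) is the
  signature of a one-nucleotide backbone translocation; values of 1–3 Å
  mean the backbone never moved a registry.
* **pore geometry** — the Cα(135)–Cα(220) distance as a pore-width
  proxy, the Cα(380)–Cα(220) distance as the Arch/lobe-1 gap, and the
  minimum heavy-atom distance between the residue-380 side chain and
  the lobe-1 helix (residues 215–221) as the closed/open gap indicator.
  These are internal distances; no superposition is involved.
* **interaction networks** — geometric hydrogen-bond occupancies
  (fraction of window frames a donor–acceptor pair satisfies the
  criterion), summed into per residue–nucleotide "total HB" numbers;
  cation-π and methyl-π contacts from ring-centroid distance and axial
  angle; van-der-Waals contact counts from a 4.5 Å heavy-atom cutoff.
* **stage segmentation** — trajectories traverse stages defined by
  which residue–nucleotide contacts exist; boundaries are changes in a
  smoothed binary contact fingerprint that persist for a minimum dwell.
* **replica classification** — each replica is labelled
  `backbone_translocation`, `base_translocation` (the base flips into
  the pore while the backbone stays), or `blocked` (entrapment), and
  replica populations are summarized as percentages.

PoreTrack implements this pipeline as reusable, tested functions, plus
a synthetic trajectory generator that plants each behavior with known
magnitude so the entire pipeline is verifiable without multi-gigabyte
trajectories.

## Units and containers

Coordinates are always Å and times always ns internally; microsecond
quantities are converted at the interface. The central objects are S4:
`Topology` (atom records, domain map, lesion flags, nucleotide position
labels), `Trajectory` (atoms × 3 × frames array with a strictly
increasing time base) and `TranslocationReport` (the per-replica
result, losslessly serializable to JSON). Time series are plain
`data.frame(time_ns, value)`.

The tandem lesion is modelled as one residue named `T64` whose two
thymine-derived rings carry `5`/`3` atom-name prefixes, so the
selections `base:5T` and `base:3T` address the two rings separately —
the two moieties are separately trackable observables.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `bdnaSpacing` | 7.0 Å | B-form adjacent P–P spacing; the one-nucleotide translocation yardstick |
| `translocationFactor` | 0.8 | backbone label threshold, as a fraction of `bdnaSpacing` |
| `baseRmsdCut` | 5.0 Å | heavy-atom RMSD floor for a base flip |
| H-bond `daCutoff` / `dhaMinAngle` | 3.5 Å / 135° | geometric hydrogen-bond criterion |
| cation-π / methyl-π cutoffs | 6.0 / 4.6 Å, 45° | ring-centroid distance and axial angle |
| vdW contact cutoff | 4.5 Å | heavy-atom contact distance; "abolished" = windowed mean count < 1 |
| contact cutoff (stages) | 4.0 Å | residue–nucleotide contact for fingerprints |
| bend factor | 1.3 | bend call when the cross-loop P–P mean ≤ 1.3 × spacing (≤ 9.1 Å) |

The backbone threshold 0.8 × 7.0 = 5.6 Å sits between the ~6.6 Å
displacement of a genuinely translocated nucleotide and the ≤ 3.6 Å
observed for non-translocated replicas, so any cut in that interval
separates the classes; 0.8 is the conservative midpoint-leaning choice
and, like every cutoff above, is exposed in `poreConfig()` /
`hbondCriterion()`. The heavy-RMSD floor of 5.0 Å reflects that
blocked-versus-flipped replicas span roughly 3–10 Å of base-driven
RMSD; RMSD alone cannot separate a flip from large in-place base
motion, which is why the flip label additionally requires the windowed
mean base centroid to lie **inside the pore**. The pore interior is
operationalized as the triangular prism spanned by the Cα centroids of
the three domain anchors (FeS helix 128–138, the Arch helix around
residue 380, and the lobe-1 helix 215–221), extruded ±6 Å along the
triangle normal — the simplest testable geometry for an opening that is
only defined by the three domains around it.

The hydrogen-bond criterion defaults (3.5 Å, 135°) are conventional
trajectory-analysis values; when the input carries no hydrogens the
criterion degrades explicitly to distance-only (`inferred` mode, the
hydrogen imagined on the donor→acceptor axis). Hydrogens are attached
to the nearest N/O/S atom of their residue within 1.3 Å — C–H
hydrogens are irrelevant to donor geometry and carbon is deliberately
excluded from attachment.

"Total HB" numbers follow the summation convention: the total for a
residue–nucleotide pair (split by backbone/base moiety of the
nucleotide-side atom) is the **sum of the occupancies of all its
donor–acceptor pairs**, and may exceed 1. A panel total over a residue
list is the plain sum of its group totals; the tests verify this
additivity exactly.

## Equilibration window

Ensemble statistics are only meaningful over the equilibrated tail of a
replica. `equilibrationWindow()` returns the earliest start time after
which every supplied series (pore Cα RMSD plus the nucleotide tracks)
has an absolute linear slope below 0.1 Å per 100 ns over a sliding
window of 10% of the trajectory; the window end is the final frame. If
no plateau exists the final 40% of frames is used with a warning — the
same fraction a 2.0–3.5 μs window represents of a 3.5 μs run. An
explicit window always overrides detection, and windows are closed
intervals. The reported spread is the per-frame standard deviation
over the window, not a block average: the mean ± SD convention of
per-frame series. (Block averaging would shrink the SD by the
autocorrelation factor; with synthetic white noise the two coincide.)

## Stage segmentation

Contacts (minimum heavy-atom distance ≤ 4 Å between a residue and a
nucleotide) are evaluated per frame, each pair's series is smoothed by
a majority filter of width 5% of the frames, and a boundary is emitted
where the smoothed fingerprint changes to a state persisting at least
`minDwell` (default 5% of the trajectory length); shorter excursions
are absorbed into the preceding stage, which makes the boundary count
monotone non-increasing in the dwell. Fingerprints, not RMSD
changepoints, define stages because the stages of interest are defined
by *which* residue–nucleotide contacts exist, not by how far something
moved.

## Representative structure

The "most representative structure" of a windowed ensemble is the
medoid: the frame minimizing the summed pairwise RMSD (after mutual
superposition on the chosen selection) to all other window frames,
with ties broken to the earliest time. The implementation is exact
(full O(n²) pairwise evaluation); the acceptance tests verify identity
with an independent brute-force evaluation on every sub-window of a
20-frame ensemble.

## The synthetic generator

`generateScaffold()` builds three rigid pseudo-domain clusters carrying
the canonical pore residues (R112, K128, H135, A139, S140, Y141, Y158,
F161, Y192, F193, R196; E377, R380, H384, N402; the lobe-1 helix
P215–V221) with Cα plus minimal side-chain pseudo-atoms — only the
atoms the detectors consume (rings, guanidinium/amine tips, carboxylate
oxygens, donors/acceptors) — threaded by a 4-nt B-form ssDNA track with
P/OP/sugar/base pseudo-atoms. Two geometric facts are planted by
construction and asserted to 1e-6: the Cα(135)–Cα(220) width equals
16.7 Å (the cryo-EM reference value of the closed pore) and the
closest approach between the residue-380 side chain and residues
219/220 equals 2.8 Å. The pore-opening event translates the lobe-1
cluster 3.6 Å along the width axis, i.e. exactly the 20.3 − 16.7 Å
difference between the open (undamaged-DNA) and closed ensemble means,
so desk tests exercise the numeric regime of the real system.

`generateTrajectory()` plants events as linear interpolations over a
50-frame transition: a backbone hop of exactly `bdnaSpacing` along the
strand axis for the position-1 phosphate; a base flip that moves the
position-1 ring centroid into the pore prism with the phosphate fixed;
pore open/close translations; and contact on/off toggles for stage
tests. Entrapment is the null scenario. Defaults are 150 frames at
10 ns spacing (a 1.5 μs cartoon of a microsecond-scale replica), event
onset at 400 ns, and Gaussian positional noise of σ = 0.5 Å per
coordinate per frame — large enough to be visible against the 2.8 Å
gap and small against the 7 Å hop, the regime in which the real
observables live. All label-recovery results are additionally checked
at σ = 1.0 Å.

Planted hydrogen bonds are realized through the donor hydrogen: per
frame a Bernoulli draw with the planted probability decides whether the
hydrogen lies on the donor→acceptor axis (angle 180°, satisfied) or
perpendicular to it (≈ 70°, rejected). The donor and acceptor heavy
atoms of planted pairs are pinned (exempt from positional noise):
noise on those two atoms would make the realized satisfaction
probability systematically lower than the planted value (at σ = 0.5 Å
the donor–acceptor distance exceeds the cutoff in ~10–20% of frames),
which would defeat the point of planting a known occupancy. The
recovery tests therefore measure exactly the binomial sampling error
they claim to.

What the generator does **not** emulate: physically realistic
dynamics, correlated motions, solvent, force-field energetics, or
sequence-dependent DNA geometry. Passing the synthetic acceptance
tests demonstrates that the *detectors and classifiers are correct*
(they recover what was planted, at the planted magnitude, under the
stated noise), not that the scientific conclusions transfer to any
particular real trajectory. Real data enter through the same
interfaces (PDB/PRMTOP-free NetCDF reading via `ncdf4`, multi-model
PDB, XYZ) with residue numbering mapped in the run configuration.

## Numerical choices and degenerate inputs

* Kabsch superposition rejects fit sets with fewer than 3 atoms or a
  collinear geometry (second singular value below 1e-8 of the first);
  the reflection branch is never taken (det = +1 enforced).
* A single-atom RMSD measure set reduces to the plain displacement
  distance, which is what the P-displacement track uses.
* Ring normals come from the SVD of the centered ring atoms; collinear
  rings are an error (no plane).
* π-contact axial angles are folded (`min(θ, 180° − θ)`) because the
  ring normal's sign is arbitrary.
* The B-form builder satisfies the chord identity
  `spacing² = (2 r sin(twist/2))² + rise²` to 1e-9 for any parameters;
  with the defaults (36°, 3.38 Å, 9.93 Å) the spacing is 7.006 Å — the
  ~7 Å yardstick. Zero twist degenerates to a straight rise, used as a
  degenerate-input test.
* Selections resolve deterministically to ascending atom positions and
  an empty resolution is an error naming the unmatched clause, never a
  silent empty set. Atoms of unknown element are treated as heavy with
  one warning.
* Equal-seed syntheses are bit-identical; the analysis report contains
  no timestamps, so re-running an identical configuration yields a
  byte-identical JSON report.

## Problem sizes in the test suite

The suite generates everything it needs at run time: 30 + 30 replicas
of 150 frames × ~220 pseudo-atoms for label recovery at two noise
levels, 20 seeds × 2000 frames for occupancy recovery, 150 randomized
dense frames for the hydrogen-bond oracle, 250 for the π oracle, 100
for the van-der-Waals oracle, and every sub-window of a 20-frame
ensemble for the medoid oracle. These sizes keep the binomial standard
errors an order of magnitude below the asserted tolerances.

## Known limitations

* PRMTOP parsing is out of scope; AMBER NetCDF frames are read against
  a topology taken from the accompanying PDB (residue-number offsets
  between the two, where they exist, are handled by the config's
  domain and nucleotide maps).
* Periodic-boundary imaging is not undone; trajectories are assumed
  imaged (intra-complex analyses).
* The classification thresholds are calibrated for the
  one-nucleotide-registry problem; sliding over many registries would
  need a registry-aware displacement track.
* The equilibration detector assumes a monotone approach to a plateau;
  oscillatory slow modes can defer the detected start, in which case an
  explicit window is the right tool.
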
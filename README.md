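# PoreTrack

Translocation and stalling analysis of helicase–ssDNA molecular-dynamics
trajectories.

Superfamily-2 helicases such as the XPD subunit of TFIIH verify bulky DNA
lesions by stalling: undamaged single-stranded DNA threads through the entry
pore formed by the FeS, Arch and ATPase-lobe-1 domains, while a bulky adduct
is gripped near the pore and cannot pass. PoreTrack implements, for R users
analysing such trajectories, the standard observable set used to tell the two
outcomes apart:

* **Per-nucleotide tracks after pore superposition.** Every frame is fitted
  onto a reference on the pore Cα atoms (Kabsch, proper rotations only);
  the displacement of a nucleotide's backbone phosphorus and its heavy-atom
  RMSD are recorded per frame. A windowed mean P displacement near the
  B-form adjacent phosphate spacing,
  d(P–P) = sqrt((2 r sin(Ω/2))² + h²) ≈ 7 Å (twist Ω = 36°, rise h = 3.38 Å),
  is the signature of a one-nucleotide 3′→5′ backbone translocation.
* **Pore geometry.** Cα(135)–Cα(220) width proxy, Cα(380)–Cα(220) gap, and
  the minimum heavy-atom distance between the Arg-380 side chain and the
  lobe-1 helix (residues 215–221).
* **Interaction networks.** Geometric hydrogen-bond occupancies summed into
  per residue–nucleotide "total HB" numbers; cation-π and methyl-π contacts;
  van-der-Waals contact counts.
* **Stage segmentation** from smoothed residue–nucleotide contact
  fingerprints, **medoid representative structures**, a **DNA bend metric**
  (cross-loop P–P distance), and **replica classification** into
  `backbone_translocation` / `base_translocation` / `blocked` with population
  tables.

A synthetic pore-scaffold generator plants each behavior with exact,
analytically known magnitudes (16.7 Å pore width, 2.8 Å closed-gap approach,
7.0 Å backbone hop, +3.6 Å pore opening, Bernoulli hydrogen-bond
occupancies), so the whole pipeline is verifiable at desk scale with no
downloads.

## Worked example

```r
library(PoreTrack)

## a replica with a planted one-nucleotide backbone hop (sigma = 0.5 A noise)
g    <- generateTrajectory(scenarioSpec(kind = "backbone_translocation", seed = 1))
traj <- g$trajectory
traj
#> Trajectory: 150 frames x 218 atoms, t = 0.000..1490.000 ns

pg <- poreGeometrySeries(traj)
st <- seriesStat(pg$width, c(1000, 1490))
sprintf("pore width: %.1f +/- %.2f A", st$mean, st$sd)
#> "pore width: 16.7 +/- 0.71 A"

topo <- topology(traj)
tr   <- nucleotideTrack(traj, g$reference, topo@positions[["1"]])
pd   <- seriesStat(tr$pDisplacement, c(1000, 1490))
sprintf("P displacement: %.1f +/- %.2f A", pd$mean, pd$sd)
#> "P displacement: 7.1 +/- 0.59 A"

classifyBehavior(tr, c(1000, 1490), topo, g$reference)$label
#> "backbone_translocation"
```

The windowed P displacement (7.1 ± 0.59 Å) reaches the ~7 Å B-form spacing,
so the replica is labelled a backbone translocation; an entrapment replica
stays near 1 Å and is labelled `blocked`. Real trajectories enter through
`loadStructure()` / `loadTrajectory()` (multi-model PDB, XYZ, AMBER NetCDF)
and the same functions apply; `runAnalysis()` orchestrates the full pipeline
from a YAML configuration and writes a versioned JSON report, per-series
CSVs and a text summary. A thin command-line wrapper lives at
`inst/cli/poretrack.R` (`analyze`, `synth`, `population` subcommands).

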
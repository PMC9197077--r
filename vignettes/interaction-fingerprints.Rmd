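---
title: "Detecting and fingerprinting nucleic acid-ligand interactions"
author: "SIFtNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and fingerprinting nucleic acid-ligand interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SIFtNA)
```

## The problem and the model

RNA and DNA molecules bind metabolites, drugs, ions and other partners
through networks of weak non-covalent contacts. SIFtNA detects these
contacts in a complex of a nucleic-acid *receptor* (a PDB model, possibly
with crystallographic waters and metal cations) and one or more *ligand*
records (a multi-record SDF with assigned protonation states and formal
charges), classifies them into interaction types under geometric
criteria, and encodes the result as a Structural Interaction Fingerprint
(SIFt): a binary vector with one bit per (residue, interaction channel),
set to 1 when at least one interaction of that type involves that
residue.

Fingerprints are computed at three resolutions:

* **SIMPLE** — one bit per residue: any heavy-atom contact within the
  contact cutoff;
* **PBS** — three bits per residue, applying the same contact criterion
  separately to the phosphate, sugar and base fragments;
* **FULL** — twelve typed channels per residue: hydrogen bonds, halogen
  bonds, cation-anion, Pi-cation, Pi-anion, Pi-stacking, four
  metal-mediated channels (magnesium, potassium, sodium, other metals),
  water-mediated, and lipophilic contacts. Plugin channels append after
  these twelve.

Bits are laid out residue-major (all channels of residue 1, then residue
2, ...), with residues ordered by chain and residue number. Residue
numbering must be unique across all chains; this is a deliberate
constraint of the file contract, and violating inputs are rejected rather
than silently renumbered.

## Geometric criteria

Every numeric criterion lives in a `GeometryConfig` and can be overridden
programmatically (`geometryConfig(hb_dist_max = 3.5)`) or from a flat
`key=value` file (`readGeometryConfig()`). The hydrogen-bond heavy-atom
cutoff of 3.9 Angstrom is the published default of this profiling
protocol. The remaining defaults are *reconstructions*: they follow the
standard interaction-profiler literature rather than a printed table, and
they are deliberately exposed as configuration so that any protocol
difference can be dialled in.

| criterion | default | meaning |
|---|---|---|
| `hb_dist_max` | 3.9 A | D...A heavy-atom distance (inclusive) |
| `hb_dha_angle_min` | 100 deg | D-H...A angle, angle-aware mode |
| `hal_dist_max` | 4.0 A | halogen X...A distance |
| `hal_don_angle` +/- window | 165 +/- 30 deg | C-X...A sigma-hole direction |
| `hal_acc_angle` +/- window | 120 +/- 30 deg | X...A-Y acceptor direction |
| `ca_dist_min`, `ca_dist_max` | 0.5, 5.5 A | cation-anion window (clash guard, cutoff) |
| `pi_stack_dist_max` | 5.5 A | ring centroid distance |
| `pi_stack_offset_max` | 2.0 A | in-plane centroid offset (parallel class) |
| `pi_stack_parallel_angle_max` | 30 deg | interplanar angle, parallel class |
| T-shape window | 60-90 deg | interplanar angle, T class |
| `pi_ion_dist_max`, `pi_ion_angle_max` | 6.0 A, 30 deg | centroid-ion distance, normal angle |
| `ion_mediated_dist_max` | Mg 3.0, K 3.5, Na 3.1, other 3.0 A | per-metal coordination legs |
| `water_mediated_dist_max` | 3.5 A | both water-bridge legs |
| `lipophilic_dist_max` | 4.0 A | apolar atom pair |
| `simple_contact_dist_max` | 4.0 A | SIMPLE/PBS contact |

Hydrogen bonds support two criteria. The default distance-only mode
(D...A) fires on the donor-heavy-atom-to-acceptor distance alone and
works on structures without hydrogens. The angle-aware mode (D-H...A)
additionally requires an explicit hydrogen on the donor with a
D-H...A angle of at least `hb_dha_angle_min`; it is more selective but
depends on how hydrogens were placed, which is why hydrogen addition
(`addHydrogens()`, OpenBabel- or RDKit-based) is an explicit, user-chosen
step and never silent. Donors lacking hydrogens in D-H...A mode are an
error rather than a silent miss.

Both interaction directions are always evaluated: the receptor acts as
hydrogen-bond donor and acceptor, and as anion (phosphate OP1/OP2, and a
5'-terminal OP3, are treated as anions regardless of recorded charge) as
well as — through its nucleobase ring faces — as the aromatic partner of
Pi-cation/Pi-anion contacts in either orientation.

## Feature perception

Ligand features are perceived through OpenBabel with SMARTS definitions
held in the configuration (and therefore overridable): donors are N/O/S
bearing at least one hydrogen; acceptors are oxygens plus nitrogens with
a free lone pair, excluding positively charged, quaternary, amide and
pyrrole-type nitrogen; halogen-bond donors are C-Cl/Br/I pairs (fluorine
is excluded — its sigma-hole is too weak to be counted by standard
profilers); charged centres come from formal charges (plus bare metal
atoms as cations); aromatic rings of size 5-6 come from the smallest set
of smallest rings, so fused systems contribute their constituent rings
independently; lipophilic atoms are C/S bonded only to C, H, S or
halogen, excluding charged atoms.

Receptor residues are typed from canonical nucleotide tables (donors,
acceptors, anionic phosphate oxygens, ring definitions), which makes
perception independent of bond-order guessing on PDB input; residues
with standard atom naming but non-canonical residue names fall back to a
geometric rule set. Two receptor-side choices deserve a note:

* **Phosphate group boundary.** The bridging O5' and O3' travel with the
  phosphate group in the PBS classification, keeping the P fragment
  chemically complete.
* **Receptor lipophilic atoms.** The strict "carbon bonded only to C/H"
  rule would leave a ribose essentially without lipophilic atoms, yet
  sugar carbons are well-documented lipophilic contact partners. The
  receptor side therefore uses a slightly wider documented rule — carbon
  with at most one single-bonded N/O neighbour and no multiple bond to
  oxygen — which admits C2'-C5', pyrimidine C5/C6 and the thymine
  methyl while keeping carbonyl and di-heteroatom carbons out. The
  ligand side keeps the strict rule.

Ring geometry uses the coordinate centroid and the unit eigenvector of
the smallest covariance eigenvalue (best-fit plane normal). Normal signs
carry no meaning; every angle criterion folds to [0, 90] degrees.

## Mediated interactions and the ion profile

Water- and metal-mediated channels bridge a receptor partner and a ligand
partner through a water oxygen or an inorganic cation *from the receptor
file* — mediators travel with the PDB. Metal channels route by element
(Mg/K/Na/other) with per-element coordination cutoffs; the recorded
distance of a mediated interaction is the longer of its two legs (the
binding leg). When no ligand file is given, every inorganic ion in the
receptor is treated as a ligand instead (`ionProfile()`), producing one
fingerprint per residue-ion pairing in which only the cation-anion
channel (FULL) or the contact bits (SIMPLE/PBS) can be set.

## Wrappers, similarity, and hot spots

`wrapSIFt()` post-processes a fingerprint: **ACUG** reports the logical
OR over residues of each nucleotide type (thymine maps onto the U row for
DNA), **PuPy** does the same for purines/pyrimidines, and **Counter**
reports per-channel residue counts (the channel's Hamming weight).

`fingerprintSimilarity()` implements the eight bit-vector metrics in
their standard binary forms, with A and B the set-bit counts and C the
overlap: Tanimoto C/(A+B-C); Tversky C/(C + a(A-C) + b(B-C)) with the
*first* argument as the reference, so Tversky(1,0) is the fraction of
reference interactions recapitulated in a model; Cosine C/sqrt(AB);
Manhattan, Euclidean, Square Euclidean and Half Square Euclidean from the
symmetric difference A+B-2C; and Soergel, the complement of Tanimoto.
Two all-zero fingerprints (a real occurrence for distant ligands) take
the 0/0 -> 0 convention with a warning, and `verbose = TRUE` exposes
(A, B, C) so any value can be audited. `distanceMatrix()` computes the
all-vs-all matrix and writes the TSV; it is symmetric for every metric
except Tversky with unequal weights.

The hot-spot module aggregates detail records — possibly pooled over many
complexes — into per-atom interaction counts with percentages per type
and per residue, phosphate/sugar/base rollups, per-type unique-residue
counts (one interaction of a given type per residue), fixed-width
distance histograms, and nucleobase face assignments. The face map
(Watson-Crick / Hoogsteen / sugar edge per base atom) is a documented
default in `defaultFaceMap()`; atoms shared between edges are assigned to
a single face and the whole table is replaceable by the user.

## Plugins

Additional interaction types are YAML definitions: a SMARTS pattern per
side plus one criterion — distance, distance + angle, or distance +
dihedral. Anchors are side-qualified 1-based positions in the match
tuples (`R2` = second atom of the receptor match); the inter-side
distance is always measured between the first atoms of the two matches.
Plugin channels append after the twelve built-in channels and can never
alter them. For canonical nucleotides the receptor residue is rebuilt
with its known topology and the phosphodiester charge before SMARTS
matching, so valence- and charge-sensitive patterns behave predictably.
The shipped sample file (`samplePluginFile()`) defines six reconstructed
types: any contact, polar, weak polar, n->pi* (a Buergi-Dunitz angle
window at the carbonyl carbon), weak hydrogen bonds, and halogen
multipolar contacts. The constants `RECEPTOR_HB_DONOR_SMARTS` and
`RECEPTOR_HB_ACCEPTOR_SMARTS` express the built-in receptor
hydrogen-bonding tables as SMARTS; a distance-only plugin pair built from
them reproduces the distance-only hydrogen-bond channel bit for bit,
which the test suite uses as a cross-validation of the whole plugin path.

## The synthetic probe generator

`makeProbeComplex()` emits a (PDB, SDF) pair realizing a requested
geometry: an idealized nucleotide template (planar base polygon, ribose,
phosphate, explicit hydrogens) and a minimal ligand probe (methanol,
ammonium, benzene, chlorobenzene, acetate, methane) placed at the
defining distance/angle/offset, with mediating waters or ions written
into the PDB when needed. All randomness — the azimuthal orientation of
the probe about its approach axis — is controlled by the seed, and
identical spec + seed give byte-identical files.

What the generator emulates is the *geometry* of each interaction class
at controllable parameters; what it does not emulate is real structural
context: conformational strain, crowded binding pockets, alternate
locations, experimental coordinate error, or modified residues. Passing
tests on probes therefore demonstrate that the geometric predicates,
encodings and outputs are correct, not that any biological conclusion
holds for a particular complex.

Two numerical points. First, the hydrogen-bond probe approaches its
receptor donor along the +x axis on the 0.001 A grid, so its defining
distance survives the fixed three-decimal PDB coordinate format exactly —
this is what makes the 3.90-vs-3.91 A boundary test meaningful on files.
Second, for general (angled) placements the PDB format itself bounds how
precisely an emitted file can reproduce a requested geometry (about
2e-3 A in a distance, 0.05 degree in an angle over bond-length lever
arms); the generator's returned in-memory geometry is exact, and
file-based checks use the format-limited tolerance.

## Numerical choices and tie-breaks

* All distance cutoffs are inclusive (`<=`); the cation-anion window is
  open below (`>`) as a clash guard.
* Detectors and the plugin engine share one distance primitive so that a
  shared cutoff breaks floating-point ties identically at the boundary.
* Pi-stacking uses the smaller of the two centroid projections as the
  offset, classifies parallel stacks as `sandwich` below 0.5 A offset and
  `parallel-displaced` otherwise, and applies no offset criterion to the
  T-shaped class.
* Records are keyed by (type, receptor side, ligand side, mediator);
  duplicates collapse, so e.g. two waters bridging the same atom pair set
  one bit and one record.
* An atom may participate in several channels at once (e.g. hydrogen-bond
  partner and water-bridge partner of the same ligand atom); channels are
  independent.
* Degenerate geometry (collinear ring atoms, zero-length normals) raises
  a typed error rather than returning NaN.

## Verification strategy and problem sizes

The test suite validates every detector against an independently written
brute-force oracle — plain loops with scalar predicate evaluation over
all qualifying feature pairs — on 200 seeded random probe complexes per
channel, with geometries drawn to straddle each criterion's cutoffs. It
further checks: mode subsumption (D-H...A detections are a subset of
distance-only detections; PBS bits imply SIMPLE bits) on 100 random
probes; exact metric identities (Soergel = 1 - Tanimoto, Tversky(1,1) =
Tanimoto, Euclidean squared = Manhattan, Tversky(1,0) = 1 exactly for
nested fingerprints) on 1000 random vector pairs; wrapper conservation
against direct recomputation on 100 random fingerprints; invariance of
all fingerprint bits under joint rigid motion on 50 seeds; and the
plugin/hydrogen-bond cross-validation on a panel of probes spanning the
cutoff boundary. These sizes were chosen to cover the decision boundaries
densely while keeping the default test run fast on a single CPU.

One integration check — reproducing published interaction totals over a
curated set of 207 experimentally solved RNA-ligand complexes — requires
structures that cannot ship with the package; it runs only when the user
stages the dataset locally (see `tests/testthat/test-acceptance.R`) and
reports a clear failure message otherwise.

## Known limitations

* Fixed, partner-independent cutoffs per interaction type; strong and
  weak hydrogen bonds are not distinguished (custom plugin types are the
  intended workaround).
* Residue numbering must be unique across chains.
* Input formats are fixed: PDB receptors, SDF ligands; ligands and buffer
  molecules must be removed from the receptor file beforehand.
* Protonation states are taken as given; no pKa-dependent protonation or
  tautomer enumeration is attempted.
* Geometric defaults other than the 3.9 A hydrogen-bond cutoff are
  literature-based reconstructions, not published values; override them
  when matching a specific protocol.
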
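---
title: "Alanine scanning of protein-RNA interfaces: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alanine scanning of protein-RNA interfaces: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the model behind `AlaScanRNP`, the assumptions it
makes, the tunable parameters and why they default to what they do, what
the synthetic-data generator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## The problem and the model

Given the structure of a protein–RNA complex, we want a per-residue
estimate of how much each amino-acid side chain contributes to RNA
binding, cheap enough to run on hundreds of complexes. The package
follows the classic computational alanine-scanning recipe: score the
complex with a pairwise potential, truncate one residue at a time to
alanine, rescore, and interpret the score difference as that side chain's
contribution. Everything rests on three components.

**1. Coarse-grained interaction centers.** Each amino acid contributes a
backbone center (the Cα position) and a side-chain center (centroid of
side-chain heavy atoms; the Cβ position for alanine; none for glycine).
Each nucleotide contributes a phosphate center (P), a sugar center (C1′)
and a base center (centroid of base heavy atoms). This representation was
chosen so that alanine truncation has a well-defined geometric effect —
the side-chain centroid collapses onto Cβ while the backbone center is
untouched — and so that partially disordered residues still yield
centers. Residues lacking the defining atoms are skipped with a warning
rather than silently invented.

**2. A decoy-referenced statistical potential.** Energies are log-odds of
pair frequencies between native complexes and rigid-body *decoys* of the
same complexes:

$$E(t, r) = -\ln\frac{f_{obs}(t,r) + \alpha}{f_{ref}(t,r) + \alpha}$$

over pair types $t$ (20 amino acids × {backbone, side chain} × 4 bases ×
{phosphate, sugar, base}) and distance bins $r$. Decoys re-pose the RNA
with a rotation uniform on SO(3) (quaternion method) and a translation
whose direction is uniform on the sphere, with the magnitude resampled
until the minimal inter-entity heavy-atom distance lies in [3, 10] Å — so
the reference ensemble consists of *in-contact but arbitrary* poses, not
separated ones. Using randomized poses of real (or realistic) complexes
as the reference state sidesteps the choice of an analytic null
distribution; the same counts-versus-counts construction guarantees that
a (type, bin) cell observed in neither set keeps $E = 0$.

The potential is distance-only. Orientation-dependent terms (the angular
preferences of, say, arginine–phosphate salt bridges) are a known
limitation; the energy-table schema keeps type and bin axes separate so
an orientation axis could be added without changing the serialized
format's shape conventions.

**3. Per-interface normalisation.** For interface residue $i$ of
interface $j$:

$$\Delta\ln(DARS)_{i,j} = \ln|DARS_{WT}| - \ln|DARS_{Ala,i}|,$$

negative values are excluded (they indicate side chains engaged in
intramolecular contacts and are reported as `excluded_negative`, not
silently dropped), and the rest are divided by their interface mean
$\bar\Delta_j$, giving interaction scores $IS_{i,j}$ with mean exactly 1
per interface. $\Delta\ln = 0$ counts as non-negative and is retained.
Thresholds: $IS > 2$ hotspot, $1 < IS \le 2$ warmspot (the 2.0 boundary
belongs to warmspots), $IS \le 1$ other. The IS scale is relative to its
own interface by construction: scores from unrelated complexes are not
directly comparable, and IS is *not* a $\Delta\Delta G$ in kcal/mol —
`correlate_with_ddg()` exists precisely to compare it against
experimental values per complex, and warns below five matched pairs where
a Pearson correlation becomes fragile.

Because the potential is a sum over protein-center × RNA-center pairs,
the wild-type complex is scored once per interface and each variant score
is obtained incrementally by exchanging the mutated residue's pair terms;
a test asserts bit-level agreement with explicit mutate-and-rescore.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| scan interface cutoff | 7.0 | Å | established optimum for protein–nucleic acid pair potentials; also the potential's $r_{max}$ |
| contact cutoff (statistics) | 4.0 | Å | conventional heavy-atom contact definition for interface composition |
| bin width | 0.5 | Å | 14 bins to 7 Å; finer bins starve counts at fixture scale |
| pseudocount $\alpha$ | 1.0 | — | Laplace smoothing; keeps unobserved cells finite and zero-centred |
| decoys per complex | 100 (training default) | — | reference counts comparable to native counts per complex |
| decoy contact range | [3, 10] | Å | in-contact reference poses |
| SASA probe | 1.4 | Å | water probe |
| SASA points/atom | 960 | — | doubling changes fixture totals by <0.5% |
| base-pair C1′–C1′ window | [8.9, 11.9] | Å | Watson–Crick geometry window |
| WC-face distance | ≤ 3.5 | Å | donor–acceptor heavy-atom distance |
| base coplanarity | ≤ 35° (or ≥ 145°) | — | plane-normal angle tolerance |
| single-strand threshold | paired fraction < 0.2 | — | motif rule, see below |
| stem | ≥ 3 consecutive pairs | — | motif rule, see below |
| redundancy threshold | identity > 0.9 | — | strictly greater: exactly 90% is kept |

## Interface geometry

Buried surface area is
$BSA = SASA_{protein} + SASA_{RNA} - SASA_{complex}$, i.e. the buried
area summed over both molecules, computed with a native Shrake–Rupley
implementation (deterministic golden-spiral point set, Bondi-type radii,
1.70 Å fallback for unknown elements). For multi-copy complexes the
caller selects the chain subset defining one interface; the package never
guesses which protein chains belong to which RNA copy.

Moiety partitioning assigns O5′ and O3′ to the sugar, so that "backbone"
= phosphate + sugar leaves the phosphate group as exactly
{P, OP1, OP2, OP3}. This split is a package convention (the atom-by-atom
assignment of the bridging oxygens is genuinely ambiguous); changing it
moves a few percent of contacts between the phosphate and sugar columns
but cannot move backbone contacts into the base class. Percentiles in
frequency reports (20th/80th) use linear interpolation between order
statistics (R quantile type 7).

## RNA motif classification

The four motif classes are defined operationally, because any
implementation must fix an algorithm somewhere. Base pairs are geometric:
C1′–C1′ distance in [8.9, 11.9] Å, Watson–Crick-face heavy-atom distance
(purine N1 / pyrimidine N3) ≤ 3.5 Å, base planes coplanar within 35°,
greedy one-partner-per-base matching by shortest WC distance.
Non-canonical pairs that satisfy the geometry are typed `other` but count
toward the paired fraction — structure, not sequence, drives the motif.
Rules, applied in order: paired fraction < 0.2 → ssRNA; ≥ 60% of pairs
interchain joining a single chain pair → dsRNA; a single chain with
exactly one stem (≥ 3 consecutive pairs) closed by an apical loop →
hpRNA; otherwise compRNA. All thresholds are exposed as function
arguments.

## Dataset curation

The filters mirror the standard assembly of a non-redundant protein–RNA
structure set: X-ray resolution ≤ 3.0 Å (3.0 itself passes; NMR entries
are exempt, and an X-ray entry without resolution metadata is dropped
with reason `metadata`), at least one protein chain of ≥ 10 residues, RNA
of ≥ 10 nucleotides, at most 50% modified nucleobases (exactly 50%
passes), ribosome exclusion, and redundancy removal. Interpretations the
package commits to: "same RNA binding partner" means exact RNA sequence
identity; redundancy groups are transitive closures of (protein identity
> 0.9 AND identical RNA); the representative is the best-resolution
entry, X-ray ranked before NMR, ties broken lexicographically by id.
Sequence identity is global alignment (match +1, mismatch 0, gap −1)
with identity = matches / length of the shorter sequence — note this
makes a perfect substring 100% identical to its parent, which is the
desired behaviour for fragment redundancy. Ribosome exclusion requires
external knowledge, so it takes a user-supplied id list and/or title
keywords rather than pretending to detect ribosomes structurally.

## Structure input conventions

NMR ensembles are reduced to model 1 (one conformer per entry; the choice
is recorded in the structure's metadata rather than averaged, since
scoring an average conformer would mix incompatible side-chain
positions). Alternate locations keep the highest occupancy, ties resolved
by file order — deterministic across runs. Hydrogens and waters are
removed; water-mediated contacts are deliberately out of scope. Modified
polymer residues map to canonical parents via a built-in ~40-entry table
(PSU→U, 1MA→A, MSE→MET, ...); unmapped HETATM polymer residues count as
modified nucleotides for the curation filter but are retained for
geometry. Chains are typed by majority residue content; an exact 50/50
split types the chain `other` and excludes it from interface analysis.

## The synthetic generator

`make_rna()` builds an idealised A-form-like lattice (twist 32.7°, rise
2.81 Å per pair) with phosphate, sugar and base heavy atoms positioned so
duplex and hairpin forms satisfy the package's own base-pair detector by
construction, plus seeded sub-Ångström jitter so different seeds give
distinct coordinates without leaving any detection window.
`make_complex()` adds a reduced protein chain (backbone N/Cα/C/O + Cβ +
one distal side-chain atom) whose side chains are planted at exact target
distances from chosen RNA moieties — the placement direction is searched
over a deterministic grid to keep every other atom ≥ 2.5 Å from the RNA —
while the remaining residues sit far outside the interface.

What the fixtures emulate: native-like contact patterns (basic side
chains on phosphates, polar contacts to sugar and base), helical base
pairing, separable interface/non-interface residues, and clash-free
packing. What they do not: real side-chain rotamers and full atom counts,
sequence-dependent base geometry, backbone connectivity at bonded
distances, crystallographic disorder, or water. Tests passing on fixtures
therefore demonstrate the *mechanics* of the pipeline — counting,
binning, normalisation, bookkeeping, invariances — and controlled
parameter-recovery properties (a planted dominant arginine attains the
maximal IS; natives outrank their decoys), not predictive accuracy on
real complexes. Accuracy claims require real structures and experimental
mutagenesis data, which the `correlate_with_ddg()` path supports.

The default potential (`default_model()`) is trained on 16 fixture
complexes whose sequences are rotated so every base occurs at the planted
contact positions and whose planted distances are spread over ~0.5 Å so
neighbouring distance bins are populated, with 40 decoys per complex and
a fixed seed — deterministic, built on first use, cached per session. It
exists so scanning works offline out of the box; for real work, retrain
on curated complexes with `train_potential()`.

## Numerical choices and degenerate inputs

* Distance bin index is `floor(d / 0.5) + 1` with the pair cutoff strict
  (`d < 7`); a pair at exactly 7 Å is not counted.
* `DARS = 0` for wild type or a variant makes `ln|DARS|` undefined; such
  residues are reported `unscorable`, excluded from $n_j$, with a
  warning. An interface where *all* residues are unscorable, or where all
  $\Delta\ln$ values are exactly zero, errors explicitly instead of
  returning an all-`NA` table.
* Scaling all energies by a positive constant leaves every
  $\Delta\ln$ — and hence every IS — unchanged; a test asserts this.
* Decoy placement retries translation magnitude and direction up to 1000
  times per decoy before erroring with advice, rather than looping
  forever on pathological geometry.
* A missing Cβ during truncation is rebuilt at ideal tetrahedral geometry
  1.52 Å from Cα using the N/Cα/C frame.
* Greedy base-pair matching breaks ties by shortest WC-face distance;
  candidate generation precedes matching, so the result does not depend
  on residue enumeration order.

## Problem sizes used by the tests

The test-suite and acceptance battery run at desk scale, chosen as the
smallest sizes at which the properties are meaningful: 10–23-nt RNAs with
12–13-residue proteins, training cohorts of 2–16 complexes, 10–100 decoys
per complex, 50 seeded fixtures for hotspot recovery and 20 held-out
fixtures (100 decoys each) for native-vs-decoy discrimination. SASA runs
at 960 points/atom with a 1920-point convergence check.

## Known limitations

* Distance-only energies; no orientation terms, no explicit hydrogen
  bonds, no water-mediated contacts.
* Rigid structures: no repacking or minimisation of either wild type or
  variants, so strain relief upon mutation is invisible.
* Side chains engaged in intramolecular networks receive negative
  $\Delta\ln$ and are excluded — a residue can be a false negative if it
  both stabilises the fold and binds RNA.
* IS is per-interface-relative; cross-complex comparisons need the
  experimental-correlation path.
* The motif classifier covers the four coarse classes only; pseudoknots
  and multi-helix junctions all land in compRNA, and no
  Leontis–Westhof pair taxonomy is attempted.
* mmCIF input and assembly/symmetry expansion are not supported; the
  asymmetric unit is analysed as given.
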
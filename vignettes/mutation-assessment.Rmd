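---
title: "Assessing cancer missense mutations on structural ensembles with psnmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cancer missense mutations on structural ensembles with psnmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnmut)
library(dplyr)
```

## The problem

A missense mutation found in a tumour sample can damage a protein in
qualitatively different ways: it can destabilise the fold (lowering cellular
levels through degradation) or it can leave the fold intact while perturbing
function — abolishing or creating regulatory modification sites, disrupting a
binding motif, interfering with functional motions, or rewiring long-range
communication to catalytic residues. Distinguishing these layers matters: a
stability mutant calls for half-life and degradation readouts, a functional
mutant for activity and interaction assays.

`psnmut` implements this layered assessment for a kinase domain whose
conformational ensemble is available (the worked case is the ULK1 kinase
domain, residues 8–280 in UniProt O75385 numbering, an upstream activator of
autophagy frequently altered in cancer genomes). The package takes a
multi-model PDB ensemble, a curated missense mutation table, a
saturation-mutagenesis ΔΔG scan, and annotation tables (REVEL scores, PTM
sites, short linear motifs, differential-expression calls), and produces a
per-mutation report with a stability score (0–2), a function score (0–5) and
a categorical verdict.

## Persistence-weighted structure networks

The structural core is the protein structure network (PSN). For every frame
of the ensemble, two residues are in contact when the distance between their
side-chain centres of mass is below 5 Å (mass-weighted heavy atoms only;
glycine falls back to Cα, alanine's centre is its Cβ). The *persistence* of
a pair is the percentage of frames in which the contact holds; pairs at or
above the 20 % persistence cutoff become edges, weighted by persistence.
Covalently adjacent neighbours (|i−j| ≤ 1) are excluded by default; the
exclusion width is a parameter because conventions differ between tools.

Hubs are nodes with degree ≥ 3 — residues whose many persistent contacts
make them structurally load-bearing. `cutoff_scan()` provides a
frame-jackknife (default 10 resamples of 80 % of frames) over candidate
distance cutoffs, reporting the stability of hub and component counts; this
is a deliberately lightweight variant of published resampling pipelines,
sufficient to justify a cutoff choice on a given system.

Salt bridges use the charged-moiety criterion: an Asp/Glu–Lys/Arg pair
interacts in a frame when any atom of the carboxylate group
(Asp OD1/OD2/CG, Glu OE1/OE2/CD) lies within 4.5 Å of any atom of the
ammonium (Lys NZ) or guanidinium (Arg NH1/NH2/NE/CZ) group. Histidine is
excluded by default and can be enabled as a basic partner. Hydrogen bonds
default to a donor–acceptor heavy-atom distance ≤ 3.5 Å with a
donor–H–acceptor angle ≥ 120° when hydrogens are present; ensembles without
hydrogens fall back to the distance criterion with a warning.

## Communication paths

Functional perturbation from a distance is assessed by shortest
communication paths on the contact PSN: for each mutation site and each
class of functional residues (activity residues, DFG/HRD/APE motifs,
C-helix, catalytic and regulatory spines), the minimum-hop path is computed;
among equally short paths the one with the higher mean edge persistence
wins, and remaining ties break lexicographically so results are
deterministic. Path length is reported as the number of intermediate nodes.
Paths are only trusted when *conserved*: present in two independently
generated ensembles (by default mere existence in both; a strict mode
requires identical node sequences). A site communicating with at least two
target classes through conserved paths is flagged as a long-range
communicator.

## Ensemble dynamics

Cα coordinates are superposed onto their mean (two Kabsch iterations) and
the 3N × 3N covariance matrix is eigendecomposed. The root mean square inner
product (RMSIP) over the first 20 eigenvectors quantifies the overlap of two
ensembles' essential subspaces (1 = identical, 0 = orthogonal). Mobile
regions are detected from the PC1 per-residue displacement profile as
contiguous stretches (≥ 3 residues) exceeding the profile mean + 1 SD; the
thresholds are explicit because such regions are often identified visually.
For ULK1 the documented mobile loops are 148–158, 172–183 and 35–41, and
`mutation_dynamics_overlap()` flags mutation sites within ± 2 residues
(configurable halo) of a mobile region.

## Stability descriptors

ΔΔG records (kcal/mol, positive destabilising) are aggregated per
(site, substitution) by averaging runs within each frame and then frames —
matching a protocol of several independent runs per representative
conformation; a flat mean is available and identical for balanced designs.
The destabilising threshold defaults to 3.0 kcal/mol: narrative treatments
of comparable scans call changes up to ≈ 1.6 kcal/mol "no effect" while
hotspot cells sit far higher, and 3.0 kcal/mol separates those regimes
cleanly; the stabilising threshold is −1.0 kcal/mol. Both are parameters
recorded in every downstream result. A site is a stability *hotspot* when
more than half of its substitutions are destabilising.

Two network criteria complete the stability layer. *Hub loss*: damaging only
when the wild-type site is a hub and the mutant-ensemble network loses that
hub behaviour; with no mutant ensemble the criterion is explicitly "not
evaluated", never silently false. *Salt-bridge loss*: damaging when the site
holds a persistent bridge and the substitution destroys charge
compatibility. Acid↔acid and base↔base swaps conserve, and acid→asparagine
conserves against both Arg and Lys partners — the amide can still coordinate
either basic group, and this reading is required to reproduce the worked
ULK1 calls (D138N conserved against K140; only R152L and D268H lose
bridges). A stricter Arg-only mode is available.

## The seven descriptors and the final scores

Stability: (1) ΔΔG destabilising, (2) network loss (hub loss OR salt-bridge
loss). Function: (3) PTM abolished, (4) PTM gained (phospho-gains gated by
relative side-chain solvent exposure ≥ 20 %, computed by Shrake–Rupley SASA
with 960 sphere points and NACCESS-style radii), (5) SLiM overlap,
(6) mobile-region overlap, (7) long-range communication. Every descriptor is
tri-state — damaging / neutral / not evaluated — and only `TRUE` counts
toward the scores, so missing analyses can never masquerade as evidence of
neutrality. The function descriptors are the five functional analyses the
assessment performs; the mapping is config-overridable. Categories follow
from the two scores: `neutral`, `stability_only`, `function_only`, `both`.
Ranking sorts by the chosen score with deterministic lexicographic
tie-breaks.

## Synthetic data and what the tests show

Every input class can be generated with planted, exactly recoverable
structure:

* `make_toy_ensemble()` realises a contact schedule deterministically — the
  first `round(p·F/100)` frames of a pair are posed in contact — so
  persistences are exact up to one-frame rounding and the PSN builder can be
  checked against an exhaustive per-frame oracle. Pseudo-residues use real
  amino-acid types (Ala/Asp/Lys/Arg/Ser/Gly) so charge rules and the COM
  fallbacks are exercised. Geometry that cannot realise a schedule is an
  error, not a silent approximation.
* `make_charged_pair_ensemble()` schedules an Asp–Lys bridge with
  sub-percent accuracy (e.g. 99.8 % over 500 frames = 499 bridged frames).
* `make_mode_ensemble()` / `make_ensemble_pair()` draw frames from planted
  orthonormal modes kept orthogonal to the rigid-body subspace, so PCA
  recovery and a target RMSIP are well defined. At 500 frames the planted
  top-2 subspace is recovered with RMSIP ≥ 0.99; at 20 frames recovery
  degrades gracefully.
* `make_ddg_scan()` plants hotspot sites at a mean effect of 8 kcal/mol over
  a 0.5 kcal/mol background (noise SD 0.3), recoverable with precision and
  recall 1 at the 3.0 kcal/mol threshold.
* `make_mutation_data()` plants one co-occurring gene pair at a requested
  odds ratio with marginal rates preserved (the 2×2 joint distribution is
  solved in closed form).

These generators emulate the *statistical* structure of real inputs —
persistence, subspace overlap, effect sizes, co-occurrence — not their
physics: there is no force field, no rotamer realism, no sequence-realistic
mutation signatures. Passing tests therefore demonstrate that the
algorithms are correct on inputs with known truth, not that any particular
biological prediction is right; validation against real ensembles is a
separate, data-dependent exercise (`ulk1_ensemble_benchmark()` reruns the
RMSIP and salt-bridge checks on the deposited ULK1 trajectories once they
are downloaded and converted to multi-model PDB).

Test problem sizes were chosen to keep the whole suite fast on one CPU
while staying in the regime where the oracles are exhaustive: toy ensembles
up to ~20 residues × 50 frames, path graphs up to 30 nodes, Fisher tables up
to 30 samples, PCA ensembles of 500 frames.

## Numerical and design choices

* Persistence thresholds compare inclusively (`>=`): a pair at exactly 20 %
  is an edge. Contact distances compare strictly (`<`).
* The ΔΔG classification is inclusive at both boundaries
  (`>= 3.0` destabilising, `<= -1.0` stabilising); categories partition the
  line.
* Residue numbering is taken verbatim from the coordinate file; mutation
  positions are matched in that numbering. No renumbering, no mmCIF.
* Alternate locations keep the highest-occupancy conformer (ties: first).
* Frame subsetting for representative conformations defaults to equal
  spacing in time; any user-chosen subset is accepted.
* The minimum-hop search is breadth-first (the target metric is hop count,
  so depth-first variants reach the same optimum); determinism comes from
  the documented tie-breaks.
* Degenerate inputs are results, not errors, where that is scientifically
  meaningful: an unreachable path target is a no-path row, a single-residue
  ensemble yields an empty graph, a never-mutated gene gives Fisher p = 1.
* Fisher's test is one-sided ("greater") by default, matching a
  co-occurrence screen; no multiple-testing correction is applied per pair
  by default, with optional Benjamini–Hochberg across a screened panel.

## An end-to-end example

```{r pipeline, eval = FALSE}
dir <- tempdir()
sched <- tibble::tibble(i = c(2L, 2L), j = c(8L, 12L),
                        persistence = c(100, 60))
ens <- make_toy_ensemble(12, sched, n_frames = 20, seed = 1)
write_pdb_ensemble(ens, file.path(dir, "toy.pdb"))
make_ddg_scan(12, hotspot_sites = 3L, seed = 2, dir = dir)

run <- run_pipeline(list(
  mutations = c("N3W", "C5V", "H9A"),
  ensemble = file.path(dir, "toy.pdb"),
  ddg_tables = file.path(dir, "scan.tsv"),
  annotation = functional_annotation(list(activity = 8L),
                                     domain_range = c(1L, 12L)),
  seed = 1))
tidy(run)
glance(run)
autoplot(run)
```

## Known limitations

* The package consumes ΔΔG tables, REVEL scores and PTM/SLiM/predictor
  outputs; it does not compute them. The energy function, pathogenicity
  model and sequence predictors are upstream tools.
* The PSN carries a single interaction weight (persistence); there is no
  interaction-energy weighting, no π-stacking or hydrophobic-cluster edge
  classes, and no centrality measures beyond degree.
* Path "average weight" is the mean edge persistence along the path — the
  only weight the network carries; other tools may normalise differently.
* Hub loss requires a mutant ensemble; generating one (by sampling or
  coarse-grained modelling) is outside the package.
* The SASA reference values are extended Gly-X-Gly side-chain areas; the
  relative-exposure gate (20 %) is conventional, not fitted.
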
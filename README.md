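# psnmut

Structure-network assessment of cancer missense mutations from
conformational ensembles.

## What it does

Tumour genomes carry many missense mutations whose mechanism is unclear: a
substitution can destabilise the protein fold (lowering cellular levels
through degradation) or leave the fold intact while damaging function —
abolishing or creating post-translational modification sites, disrupting a
short linear motif, perturbing functional motions, or cutting long-range
communication to catalytic residues. `psnmut` separates these layers for a
kinase domain whose conformational ensemble is available, producing a
per-mutation stability score (0–2), function score (0–5) and categorical
verdict. The worked case throughout is the ULK1 kinase domain (residues
8–280, UniProt O75385), an upstream activator of autophagy; the curated
pan-cancer table of its 36 kinase-domain missense mutations ships with the
package (`ulk1_mutations()`).

The quantitative core:

* **Persistence-weighted protein structure networks.** Residues are nodes;
  a pair is an edge when its side-chain centre-of-mass distance is < 5 Å in
  ≥ 20 % of ensemble frames, the edge weight being that persistence. Hubs
  are nodes of degree ≥ 3. Salt bridges use the charged-moiety rule (any
  carboxylate atom within 4.5 Å of any ammonium/guanidinium atom), hydrogen
  bonds a 3.5 Å / 120° geometric criterion.
* **Communication paths.** Minimum-hop paths from each mutation site to
  five classes of functional residues (activity residues, DFG/HRD/APE
  motifs, C-helix, catalytic and regulatory spines), kept only when
  conserved across two independent ensembles; sites reaching ≥ 2 classes
  are long-range communicators.
* **Essential dynamics.** Cα-covariance PCA with the subspace overlap of
  two ensembles measured as
  RMSIP = sqrt( (1/n) Σᵢⱼ (vᵢ·wⱼ)² ) over the first n = 20 components, and
  mobile-region detection from the PC1 displacement profile.
* **ΔΔG aggregation.** Saturation-mutagenesis free-energy tables averaged
  over runs within frames, then frames; destabilising at ≥ 3.0 kcal/mol,
  hotspot sites where > 50 % of substitutions destabilise; plus two network
  stability criteria (hub loss, salt-bridge charge-compatibility loss).
* **Genomics layer.** MAF/TSV mutation parsing, kinase-domain filtering,
  REVEL classification (damaging ≥ 0.4), PTM/SLiM annotation gated by
  Shrake–Rupley solvent exposure, differential-expression calls, and
  one-sided Fisher's exact tests for mutation co-occurrence.

Every result is a tibble; fitted objects have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` views, so the pieces chain with the pipe.

## A worked example

A 12-residue toy ensemble with two planted contacts, a planted ΔΔG hotspot
at site 3, and three mutations to assess:

```r
library(psnmut)
dir <- tempdir()
sched <- tibble::tibble(i = c(2L, 2L), j = c(8L, 12L), persistence = c(100, 60))
ens <- make_toy_ensemble(12, sched, n_frames = 20, seed = 1)
write_pdb_ensemble(ens, file.path(dir, "toy.pdb"))
make_ddg_scan(12, hotspot_sites = 3L, seed = 2, dir = dir)

tidy(build_contact_psn(ens))
#> # A tibble: 2 × 6
#>   i     j     resno_i resno_j type    persistence
#>   <chr> <chr>   <int>   <int> <chr>         <dbl>
#> 1 D2    D8          2       8 contact         100
#> 2 D2    G12         2      12 contact          60

run <- run_pipeline(list(
  mutations = c("N3W", "C5V", "H9A"),
  ensemble = file.path(dir, "toy.pdb"),
  ddg_tables = file.path(dir, "scan.tsv"),
  annotation = functional_annotation(list(activity = 8L),
                                     domain_range = c(1L, 12L)),
  seed = 1))
run
#> <psnmut_run> 3 mutations; categories: neutral=2, stability_only=1
```

The planted contacts come back with exactly their scheduled persistences,
and the report shows why each verdict was reached: `N3W` hits the planted
ΔΔG hotspot (`ddg_damaging = TRUE`, stability score 1, `stability_only`),
while `C5V` and `H9A` trigger nothing and stay `neutral`. Descriptors whose
inputs were absent (here the hub-loss criterion, which needs a mutant
ensemble) are reported `NA` — "not evaluated" — and never counted as
evidence of neutrality.

```r
dplyr::select(tidy(run), mutation, ddg_damaging, network_loss,
              stability_score, function_score, category)
#> # A tibble: 3 × 6
#>   mutation ddg_damaging network_loss stability_score function_score category
#> 1 N3W      TRUE         FALSE                      1              0 stability_only
#> 2 C5V      FALSE        FALSE                      0              0 neutral
#> 3 H9A      FALSE        FALSE                      0              0 neutral
```

On the curated ULK1 table:

```r
mu <- ulk1_mutations() |> filter_domain()
length(unique(mu$protein_change))   # 36
table(revel_classify(mu$revel))     # damaging 12, neutral 24
```

## Documentation

The methods vignette (`vignettes/mutation-assessment.Rmd`) describes the
model, its assumptions, the tunable thresholds with their defaults and
rationale, what the synthetic generators do and do not emulate, and known
limitations.
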
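---
title: "Computer-assisted antibody affinity maturation with abmature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computer-assisted antibody affinity maturation with abmature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Therapeutic antibodies usually need affinity maturation before they are
viable drugs. The classical route — display libraries, error-prone PCR,
months of panning — can be shortened by letting structure-based ΔΔG
predictors nominate point mutations and reserving wet-lab effort for a
short list. `abmature` implements such a campaign as a reusable, testable
pipeline. The motivating system is an anti-TSLP antibody (TSLP is the
epithelial cytokine upstream of asthma inflammation) whose blocking potency
is benchmarked against tezepelumab (AMG157), but every component is
generic: any antigen–antibody complex with two ΔΔG predictors and a
cell-blocking assay fits the same mould.

The campaign proceeds in rounds:

1. **Model plausibility.** A docked complex is checked against an
   experimental alanine scan: binding-critical residues should sit at the
   computed interface (`find_interface_residues()`,
   `validate_docking_model()`).
2. **Key residues.** Computational alanine scans from two predictors are
   thresholded and reconciled with the experimental scan
   (`computational_alanine_hits()`, `derive_key_residues()`).
3. **Saturation triage.** Every key residue is mutated to the other 19
   amino acids and the candidates pass through five screening criteria,
   then a second-predictor cross-check (`enumerate_substitutions()`,
   `apply_screening()`, `crosscheck_predictors()`).
4. **Assay and ranking.** Selected strains are expressed and assayed; 4PL
   fits extract IC50s and the ranking against the benchmark picks the
   round winner (`fit_4pl()`, `rank_candidates()`,
   `select_round_winner()`).
5. **Combination.** Beneficial singles are combined pairwise on the
   winning background and re-assayed (`combine_mutations()`,
   `run_combination_round()`).

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the exported functions,
which is where every computation lives. There is deliberately no shell
wrapper — the campaign is a sequence of analyses, not a command-line tool,
so the functions and scripts are the interface.

## Screening model

A candidate point mutation survives triage only if all five criteria hold
(all are evaluated and recorded for every candidate; nothing
short-circuits):

1. the mutant is not **proline** (too rigid for a CDR loop);
2. the mutant is neither **methionine nor tryptophan** (oxidation-prone);
3. the mutated sequence introduces **no new liability motif**:
   N-glycosylation sequons `NxT`/`NxS`, deamidation dimers
   `NS`/`NG`/`NH`, isomerization dimers `DS`/`DG`/`DD`, cleavage dimers
   `DQ`/`NS`;
4. the wild-type residue lies within **3.0 Å** (heavy atoms) of the
   antigen — a mutation far from the interface cannot strengthen it;
5. the predictor's sign-normalized improvement is at least
   **1.0 kcal/mol** (mCSM-PPI2 role).

A survivor is then *confirmed* only if the second predictor (Geo-PPI role)
also predicts an improvement strictly greater than 0; with no record the
cross-check abstains (`not_run`) and the verdict stands, flagged.

Notes on deliberate interpretation choices:

* **Criterion 3 compares against the wild type.** Excluding candidates for
  motifs already present in the parent sequence would disqualify
  unrelated mutations, so only *new* findings count.
* **Criterion 4 keeps the boundary.** The exclusion rule is "more than
  3 Å away", so exactly 3.0 Å is retained.
* **Criterion 5 uses signed improvement, not absolute value.** The
  alanine-scan stage, by contrast, thresholds absolute ΔΔG (|ΔΔG| > 1 for
  mCSM-PPI2, > 5 for FoldX, strict inequalities): an alanine scan asks
  which residues *matter*, triage asks which mutations *help*.
* **Sign conventions are never guessed.** Every ΔΔG record carries an
  explicit convention flag (`positive_improves_binding` or
  `positive_destabilizes`) and is normalized internally so that positive
  always means better binding.
* **The sequon wildcard is literal by default.** `NxP T/S` sequons are
  normally not glycosylated, but the screening rule as stated reads "x =
  any residue"; `sequon_x_excludes_proline = TRUE` switches to the
  biochemical rule. `X` (unknown residue) never matches the wildcard.
* **Positions are 1-based** throughout, as is idiomatic in R; liability
  findings report the 1-based start of the match.

### Key-residue reconciliation

Pure intersection of computational and experimental alanine-scan hits is
too conservative in practice: published key-residue tables routinely
contain positions the experimental scan never probed. `derive_key_residues()`
therefore defaults to `computational_then_experimental`: the union of the
two computational hit sets defines the key set, with experimental hits
recorded as corroborating provenance flags; the pipeline additionally
keeps only key residues at the antibody-side interface. The stricter
`intersect` mode and the permissive `union` mode remain available.

## Geometry

* **Interface** (default cutoff 4.5 Å): a residue is interfacial iff its
  minimum heavy-atom distance to the partner group is at most the cutoff.
  4.5 Å is the conventional heavy-atom interface definition; the triage
  proximity rule uses its own 3.0 Å threshold (`threshold_config()`).
  Hydrogens are retained when present but ignored by all distance rules —
  docking poses usually lack them.
* **Contact typing** (LigPlot-style defaults): a hydrogen bond is any
  N/O/S–N/O/S heavy-atom pair within 3.35 Å; a hydrophobic contact is a
  pair of apolar carbons (sidechain carbons of A,V,L,I,P,F,M,W plus the
  CB of every residue — stated exactly so tests can be exact) within
  3.90 Å; every other cross-group heavy-atom pair within 3.90 Å is
  `other`. This suffices to describe qualitative shifts such as a
  hydrogen bond giving way to hydrophobic packing after mutation.
* **Trajectories** arrive as multi-model PDB (one MODEL per frame); the
  MD engine is out of scope. Every frame is superposed on the reference
  by least-squares (Kabsch) before metrics: RMSD per frame over the
  selection, RMSF per residue as the RMS deviation of its atoms from
  their window-mean position (the window is typically the stable tail of
  the run). Residue identity everywhere uses author numbering exactly as
  in the file; no Kabat/IMGT renumbering is applied, and chain roles
  (antigen/heavy/light) are always supplied by configuration, never
  inferred.

## Dose–response model

Blocking assays are fitted with the four-parameter logistic

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + (x/\mathrm{IC50})^{h}}$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) on
log-concentration with a log-IC50 parameter (IC50 > 0 by construction).
Initialization is multi-start from the data: asymptotes from the
extreme-dose responses, IC50 starts at the dose quantiles plus the
midpoint crossing, Hill slopes 0.5/1/2; the best residual sum of squares
wins and the `converged` flag is honest. Curve orientation is
auto-detected and normalized (positive Hill, top ≥ bottom) since blocking
assays fall with dose but the code never assumes it. A flat response is
an error ("no dose effect"), not a fit. IC50 units are opaque assay
units; IC50s are only ever compared within one assay run, and
"better than benchmark" is a strict inequality. Rank ties break
alphabetically and are logged.

At the simulation settings used in the acceptance checks (8 log-spaced
doses, additive Gaussian noise with sd 0.02 on a unit-range curve, single
replicate) the median relative IC50 error computed by
`scripts/acceptance.R` is about 6%; this equals the error of a reference
fit started at the true parameters, i.e. it is the statistical floor of
the design, not fitting loss. Replicates reduce it roughly by the usual
square-root factor, which is why the synthetic assay stages in
`analysis/` use triplicate wells — standard practice for cell-based
blocking assays.

## What the synthetic data emulates — and what it does not

The generators exist so that every stage has exact ground truth:

* `make_toy_complex()` builds idealized CA–CB–CG "stick" residues on a
  10 Å lattice with small jitter. Antibody chains sit > 50 Å from the
  antigen except for *planted* contact residues, placed so their closest
  heavy-atom distance to the partner equals the requested value within
  ±0.1 Å; all other cross-group residues are > 6 Å apart. Interface
  detection on such a complex has a known exact answer.
* `simulate_ddg_tables()` plants true improvements for chosen mutations
  (0 elsewhere), applies per-predictor gain, Gaussian noise and sign
  convention. With zero noise, triage must recover exactly the planted
  set — this is the end-to-end recovery test.
* `simulate_experimental_scan()` applies independent false-positive /
  false-negative Bernoulli flips to the true key set.
* `simulate_dose_response()` draws 4PL curves with known IC50 and
  additive noise.

Every generator is a pure function of its arguments with a single integer
seed and locally scoped RNG (`withr::with_seed`), so identical calls give
byte-identical outputs and nothing disturbs the caller's RNG stream.

What passing these tests shows: the set logic, thresholds, distance
rules, fitting and ranking machinery are correct against independent
oracles (all-pairs brute force for interfaces, sliding-window scan for
liability motifs, rotation-grid search for superposition, closed-form
curve inversion for 4PL). What it does *not* show: anything about real
protein chemistry. Toy residues have no realistic packing, the ΔΔG
"predictors" have no biophysics, and planted assay effects are
log-additive by construction. Real campaigns inherit the error profiles
of the actual predictors and assays.

## Problem sizes and numerical choices

The default test and acceptance runs use 100 seeded complexes of 70
residues for the interface oracle, 1 000 random sequences (length ≤ 60)
for the liability oracle, 200 noisy curves for IC50 recovery, and a
4-site × 19-mutant triage round — sizes chosen so the full suite
exercises every code path in well under a minute on one CPU while keeping
Monte-Carlo assertions stable across seeds.

Other numerical conventions: PDB coordinates round-trip at 3 decimals
(PDB fixed columns); altloc resolution keeps the highest occupancy, ties
to the first listed; multi-model files use model 1 unless read as a
trajectory; non-standard residues map to `X` in sequences by default so a
liability scan never sees a silently remapped residue; duplicate key
residues deduplicate before enumeration; candidate order is
deterministic (chain, position, mutant alphabetical).

## Known limitations

* Sequence positions are assumed to equal residue numbers within each
  chain (true for the synthetic complexes and for consecutively numbered
  chains); structures with gapped author numbering need renumbering
  before triage.
* Contact typing knows hydrogen bonds and hydrophobic contacts only; no
  salt bridges, π-stacking or buried-surface-area analysis.
* mmCIF, assemblies and binary MD trajectory formats are out of scope;
  trajectories must be multi-model PDB.
* IC50 comparisons carry no uncertainty beyond the fit RSS; formal
  confidence intervals on IC50 ratios are not computed.
* The published key-residue tables of the motivating campaign cannot be
  reproduced exactly by any fixed set rule (they reflect supplementary
  data and, likely, expert judgment); the pipeline reports its own counts
  and never asserts equality with them.
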
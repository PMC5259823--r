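---
title: "Quantitative interface propensities and patch-based interface prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative interface propensities and patch-based interface prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiprop)
```

## The problem

Protein–protein interfaces differ from the rest of the protein surface
in residue composition, secondary structure, solvent accessibility and
inter-residue contacts. Naive composition comparisons are confounded by
solvent accessibility: interface residues are, by definition, exposed
in the unbound form, so comparing them against *all* residues mixes an
exposure effect into every propensity. `ppiprop` follows the approach
of comparing interfaces against the **non-interface surface** — the
exposed residues that do not participate in binding — which removes the
exposure bias and yields propensities that can be used quantitatively
in prediction.

Two components are provided:

1. **Interface analysis.** Given bound complexes partitioned into two
   sides, extract the interface and compute relative interface ratios
   (RIR) by residue type, secondary-structure state, the 60 combined
   classes, and per-type ASA classes; inter-chain contact frequencies
   and preferences; and interface/domain size statistics.
2. **SPR prediction** (Single domain based Patch Recognition). On an
   unbound domain, grow and merge candidate surface patches and rank
   them with a four-term empirical score; the top patch is the
   predicted interface.

## Definitions and the model

All thresholds default to the printed values of the method:

| Quantity | Rule | Default |
|---|---|---|
| Surface residue | per-residue ASA in the unbound domain | > 1 Å² |
| Interface residue | ASA loss on complexation **and** a cross-side heavy-atom contact | ΔASA > 1 Å², distance < 5 Å |
| Distance-matrix cap | minimum side-chain heavy-atom distance (Cα for Gly) | 25 Å |
| Solvation probe sphere | radius of the per-residue test sphere | 1.2 Å |
| Solvent probe | Shrake–Rupley probe radius | 1.4 Å |

With `f_i` interface counts and `F_i` non-interface surface counts of
class `i`, the frequencies are `w_i = f_i / Σf` and `W_i = F_i / ΣF`,
and the **relative interface ratio** is `RIR_i = w_i / W_i`. The
packaged 20-value table of residue-type RIRs (the quantitative
interface propensity index, QIPI) is available as
`spr_constants()$qipi`; it can be regenerated on any annotated dataset
with `rir_by_type()`.

Contact preferences compare the observed frequency of an unordered
residue-type pair among cross-interface contacts with the
random-mixing expectation. We count each contacting residue pair once;
the null expectation for distinct types `i ≠ j` is `2 w_i w_j` (two
orderings) and `w_i²` on the diagonal, and the preference is the log2
ratio. With that multiplicity factor, contacts drawn proportionally to
`w_i · w_j` give preferences near zero in *every* cell, which is the
property the statistic is meant to have; omitting it would pin the
diagonal near −1 under the same null. Cells with no observed contacts
are reported `NA`, never zero-filled.

The per-type ASA threshold `A_t` is located where the normalized ASA
histograms (5 Å² bins) of interface and non-interface residues cross:
the lower edge of the first bin at which the sign of
`p_interface − p_noninterface` flips. Note that two *uniform* ASA
distributions cannot cross inside their overlap (their densities are
parallel), so a crossing necessarily lands on a support edge and one
cell of the 2×2 count table is empty; the implementation flags the
ASA-RIR `NA` in that case rather than inventing a value.

## The SPR predictor

1. **Surface.** Shrake–Rupley ASA; residues with ASA > 1 Å².
2. **Distance matrix.** Minimum side-chain heavy-atom distances,
   Cα–Cα for glycine, capped at 25 Å.
3. **Growth.** For each seed, neighbours join when their distance bin
   and ASA satisfy: (2,5] → >0, (5,7] → >20, (7,9] → >40,
   (9,11] → >60, (11,13] → >80, (13,15] → >100 Å². We read the printed
   bins as half-open; distances ≤ 2 Å join unconditionally and
   distances > 15 Å never join (closed-world completion of the printed
   table).
4. **Merging.** The identity ratio is `|P₁ ∩ P₂| / min(|P₁|, |P₂|)`
   (the printed rule names no denominator; the min makes the ratio
   symmetric and the thresholds attainable). The threshold depends on
   domain ASA: ≤5000 → 0.8, ≤7500 → 0.7, ≤10000 → 0.6, else 0.5.
   Merging repeatedly unions the highest-ratio admissible pair, with
   ties broken towards the lexicographically smallest member sets, so
   the fixpoint is deterministic. Merged patches are plain unions; they
   are not re-grown.
5. **Scoring.** `E_patch = E_res + w₁E_hydro + w₂E_cons + w₃E_sol`:
   - `E_res = Σ ASA_i · RIR_r / REF_r` with `REF_r` the JANJ780101
     average accessible area. The printed formula is ambiguous about
     whether `ASA_i` is absolute or relative; we use absolute Å²
     (division by `REF_r` already non-dimensionalizes the term).
   - `E_hydro = Σ H_r` over the CASG920101 hydrophobicity potential.
   - `E_cons = Σ (C_ir − B_rr)`: PSSM self-substitution score minus the
     BLOSUM62 diagonal. PSSMs are read from PSI-BLAST ASCII files
     (first 20-column block); without a PSSM the term is disabled and
     contributes 0.
   - `E_sol`: per member, a 1.2 Å sphere at the centroid of its
     solvent-exposed heavy atoms; `V_out` is the sphere volume outside
     the solvent-accessible spheres of all atoms *other than the
     member's own*, and the term is `V_out / (V_sphere − V_out)`,
     capped at 1e6 for a fully external sphere. Own atoms must be
     excluded: the centroid always lies within the member's own
     accessible spheres, so including them would make the term
     identically zero. The volume fraction is integrated on a
     deterministic midpoint grid (0.2 Å spacing); a node-centred grid
     would share lattice planes with flat boundaries and bias the
     estimate.
6. **Ranking.** Highest `E_patch` wins; ties prefer the larger patch,
   then the lexicographically smallest member set. There is no RNG
   anywhere in the pipeline, so predictions are bit-reproducible.

Weight training maximizes the mean per-case `F = COV · ACC` of the
top-ranked patch over an exhaustive grid (default
`{0, 0.25, 0.5, 1, 2}` per weight), with ties towards the smallest
`(w₁, w₂, w₃)`. Cross-validation splits cases with a seeded
deterministic shuffle. The shipped defaults
(`w₁ = 0.5, w₂ = 2, w₃ = 0.25`) are the grid argmax trained once on 16
synthetic cases from the packaged generator; because the generator's
toy PSSMs plant conservation directly on true interfaces, `w₂` trains
high on synthetic data — on real profiles the weights should be
retrained (`train_weights()`) or supplied via a JSON file.

## The synthetic generator

`make_toy_complex()` builds two chains from ideal backbone internal
coordinates (helix φ/ψ = −60/−45, strand −120/130, or seeded
random-coil torsions) with simplified side chains: a tetrahedrally
placed Cβ extended by 0–4 pseudo-carbons according to residue size.
The second body is rotated to face the first and docked at the
separation (scanned in 0.5 Å steps) whose cross-contact fraction best
matches the requested `interface_fraction`; an unreachable fraction is
an error, not a silent adjustment. Residue types at the contact face
are drawn with the requested enrichment factors (default: Arg, Phe,
Met, Trp, Tyr at 3×); elsewhere the composition is uniform.

The **planted truth** is the set of residues having a solvent-exposed
heavy atom (unbound atom-level ASA > 5 Å²) within 5 Å of the other
side, recorded from the final coordinates. Gating on exposure matters:
a buried atom can sit within 5 Å of the partner without losing any
accessible area, and such residues are not interface by the ΔASA
criterion. With the gate, the extractor recovers ~99–100% of planted
residues on default geometries.

The default `n_per_side = 40` is chosen so that a toy domain carries
several (typically 3–5) distinct candidate patches after merging; at
20–30 residues everything merges into one patch and patch ranking is
degenerate. Toy domains are an order of magnitude smaller than real
domains (~2–7·10³ vs ~9·10³ Å² average), and the fixtures do not
emulate real packing, rotamers, electrostatics, sequence families or
experimental noise. Passing tests therefore demonstrate the
correctness of the definitions, formulas and pipeline mechanics — not
predictive performance on real structures.

## Numerical choices and degenerate inputs

- ASA uses a deterministic Fibonacci lattice (default 960 points,
  error ≲1% against closed forms and ≲3% against dense sampling);
  there is no RNG, so results are bit-identical across runs.
- Van der Waals radii: Chothia-style by element (C 1.87, N 1.65,
  O 1.40, S 1.85 Å), 1.80 Å for unknown elements; the external ASA
  program named by the method is reproduced by contract (probe 1.4 Å),
  not bit-matched, as its parameters are not printed.
- Secondary structure: a DSSP file, when given, overrides via the
  standard 8→3 mapping (H/G/I→H, E/B→E, else C). The built-in assigner
  uses dihedral runs: helix = run ≥ 4 with φ ∈ [−100°, −30°],
  ψ ∈ [−80°, 0°]; strand = run ≥ 3 with φ ∈ [−180°, −40°],
  ψ ∈ [60°, 180°] ∪ [−180°, −170°]; residues with missing backbone
  atoms are coil.
- Zero-count propensity cells are flagged `NA` by default; a
  pseudocount is available but never applied silently.
- Empty-set evaluation conventions: empty truth and empty prediction
  score 1/1; a non-empty prediction against empty truth has undefined
  coverage and zero accuracy; an empty prediction against non-empty
  truth scores 0/0.
- Alternate locations resolve to the highest occupancy (ties → altloc
  "A"); MSE is remapped to Met; other nonstandard residues are kept
  for geometry but excluded from propensity counts.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
toy <- make_toy_complex(fixture_spec(seed = 1))
cx  <- assign_secondary_structure(read_structure(toy$pdb))
ann <- extract_interface(complex_partition(cx, "A", "B"))
ann
rir_by_type(ann)

case <- toy_unbound_case(fixture_spec(seed = 1))
top  <- predict_interface(case$struct, pssm = case$pssm)
evaluate_prediction(top, case$truth)
```

The test suite exercises every operation against independent oracles
(seeded random sphere sampling for ASA, Monte-Carlo volume integration
for the solvation primitive, plain-loop recounting for the propensity
formulas), and `scripts/acceptance.R` recomputes the headline
quantities from scratch (problem sizes: 20 five-atom ASA clusters, 20
analysis complexes, 30 prediction domains, 10 cross-validation cases).

## Limitations

- The solvation term is a curvature proxy adapted to residue level
  from a ligand-scoring context; its residue-level anchoring
  (exposed-atom centroid) is our design choice and mostly yields small
  values for flat surfaces.
- The predictor reports a single top-ranked patch; domains with
  multiple independent interfaces will at best be covered partially
  (the ranked list is available as `attr(, "ranked")`).
- Patch scores are extensive (sums over members), so larger patches
  score higher at equal composition — a property inherited from the
  method, visible in its coverage-heavy, accuracy-light operating
  point.
- mmCIF input, hydrogen placement and bit-exact reproduction of the
  external ASA/DSSP programs are out of scope.
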
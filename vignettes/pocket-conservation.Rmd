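---
title: "Measuring the structural conservation of protein pockets across a family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the structural conservation of protein pockets across a family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketconserve)
```

## The question

Ligand-binding pockets that persist at the same position across many solved
structures of a protein family are strong candidates for functional sites —
and a pocket that is structurally conserved but *not* conserved in sequence
can point to an allosteric site that purely evolutionary analyses would miss.
`pocketconserve` quantifies this: it detects pockets on each representative
structure of a family, superimposes the representatives, groups pockets that
occupy the same spatial position, and scores each group by the fraction of
the family that carries it.

## The procedure, stage by stage

**Quality filtering and representatives.** Crystallographic entries need a
resolution of 3.0 Å or better; non-NMR entries without a resolution value are
discarded, as are chains spanning fewer than 30 residues and entries carrying
a stereochemistry G-factor below −1.00 (the G-factor is optional per-entry
metadata; this package does not evaluate stereochemistry itself). Because
heavily studied proteins are over-represented in structure databases, members
are grouped by complete-linkage hierarchical clustering on pairwise sequence
identity, cut so that every within-group pair is at least 95% identical, and
each group contributes its best-resolution member as a representative.
Identity is measured as identical positions over the full global-alignment
length — a simple, symmetric convention; NMR entries rank below any numeric
resolution. The reference structure is the representative with the longest
sequence, with resolution as the second criterion and lexicographic id as the
final tie-break, so the choice is deterministic.

**Superposition.** Every representative is rigidly fitted onto the reference
by a Kabsch (SVD) least-squares superposition over corresponded Cα atoms.
Correspondences default to the identically aligned columns of a global
sequence alignment with the reference; callers may supply their own pairings
or declare the coordinates pre-superimposed. The family's average post-fit
RMSD, `avg_rmsd`, measures its structural fluctuation; a family with a single
representative has `avg_rmsd = 0` by definition. This sequence-anchored fit
replaces sequence-independent structural alignment; within a family —
where sequences are homologous by construction — the two agree well, but the
package will not superimpose proteins whose sequences cannot be aligned.

**Pocket detection.** A rectangular grid (default 1.0 Å spacing, 8 Å margin)
is laid over the structure. Grid points within `probe_radius + atom_radius`
(1.6 + 1.7 Å) of any Cα pseudo-atom are *protein*; every other point is
*solvent*. Each solvent point is scanned along seven directions (three axes,
four cube diagonals) and counts the directions on which protein encloses it
on both sides — its protein–solvent–protein (PSP) count. Points with PSP ≥ 5
are pocket points; 26-connected components of at least 30 points become
pockets, ranked by size (grid-point count) and truncated at 10 per structure.
A pocket is summarized by its center of mass and its size, and its residues
are all those with a Cα within 8 Å (closed boundary) of the center. This is
the classic PSP formulation on the Cα trace: it reproduces cavity centers and
relative sizes faithfully (the package's hollow-shell fixtures verify the
center to within one grid spacing) but is not atom-complete, so absolute
pocket volumes differ from detectors that see side chains. Externally
computed pocket tables can be supplied instead, making every downstream stage
detector-agnostic.

**Family clustering.** Pocket centers from all representatives (in the
reference frame) are clustered greedily with a *family-specific threshold*:
2.0 Å plus the family's `avg_rmsd`, so structurally noisier families cast a
wider net. Every element's score is its own size plus the sizes of all
neighbors within the threshold; the highest-scoring element founds a cluster
containing all of its current neighbors, the members leave the pool, scores
are recomputed, and the process repeats until the pool is empty. The
algorithm does not distinguish pockets from different structures or the same
structure. Score ties break on ascending pocket id, which makes the partition
deterministic.

Each cluster is then scored with two quantities:

- structural conservation `Str_c = 100 · n_r / m`, where `n_r` counts the
  representatives contributing at least one member pocket and `m` is the
  number of representatives — the family coverage of the pocket;
- cluster score `Score_c = (Σ size_i / n_c) · Str_c`, the mean member size
  weighted by coverage, which ranks the clusters (ties by coverage, then
  founder id).

`Str_c` is kept on the percent scale throughout. Whether coverage enters the
score as a fraction or a percentage only rescales it and never changes the
ranking; the score lives in one function so an alternative form is a one-line
change.

**Sequence conservation.** From a family alignment, sequences receive
Henikoff position-based weights (at each column a sequence gets
`1/(r·s)`, `r` distinct symbols in the column, `s` copies of its own symbol;
sums normalized to the sequence count). Each column's weighted Shannon
entropy is computed over the 20 amino acids with the gap as a 21st symbol —
gappy columns are thereby penalized, matching the intuition that unalignable
positions are unconserved. Scores are the inverted, standardized entropies,
`(mean H − H) / sd(H)`, so conserved columns score high; a constant-entropy
alignment scores zero everywhere. Scores map onto a structure through its
alignment row (exact ungapped match) or through a global pairwise alignment
to the closest row; residues in gap regions stay uncovered.

**Significance tests.** A pocket is *significantly conserved in sequence*
when a one-sided Wilcoxon–Mann–Whitney test finds its residues' scores
stochastically greater than the scores of *all* residues in the structure at
p ≤ 0.05. Flexibility works the same way on normalized B factors
`B′ = (B − ⟨B⟩)/σ(B)` (sample SD; NMR ensembles first superimpose all models
onto the first, take the per-residue RMSF about the ensemble mean, and
convert via `B = 8π²/3 · RMSF²`): significantly higher B′ marks the pocket
*flexible*, significantly lower *rigid*, otherwise *neither*. Following the
method's wording literally, the background includes the pocket's own
residues. This overlap makes both tests mildly conservative: at a 200-residue
structure with 12-residue pockets the realized type-I error is ≈ 0.04 at
nominal 0.05 (the acceptance checks recompute this). Degenerate inputs
(constant scores) return p = 1 rather than erroring.

**Electrostatics.** The potential at a pocket center is a Debye-screened
Coulomb sum over ±1 e point charges on Asp/Glu (−) and Lys/Arg (+) Cα
positions: `φ = (l_B/ε) Σ q_i e^{−r_i/λ_D}/r_i` in kT/e at 298 K
(`l_B = 560.74 Å` in vacuum units, ε = 80, λ_D = 8 Å, distances floored at
1 Å). This is a deliberately simple point-charge model whose sign and
relative magnitude separate charged from neutral pockets; its absolute
values are **not** comparable to finite-difference Poisson–Boltzmann
potentials.

**Active sites and the threshold benchmark.** Annotated active-site residues
(typically 1–3) map to the pocket containing the majority of them; the case
is *ambiguous* when more than one pocket contains any annotated residue, and
majority ties map to none. The *active-site cluster* is the cluster holding
the most mapped pockets. The benchmark sweeps a fixed base distance `v`
(default 0–10 Å, added to each family's `avg_rmsd`, or used alone), clusters
each family, and reports the percentage of active-site pockets recovered
into the active-site cluster against the percentage of non-active-site
pockets swept in — recall versus contamination, pocket-weighted across
families by default with a per-family-average option.

**Allosteric candidates.** Pairs of clusters that are both structurally
conserved (default `Str_c ≥ 50%`) and at least 8 Å apart (centroid distance,
closed bound) are reported as candidate functional/allosteric site pairs,
optionally also requiring a sequence-conservation floor or that exactly one
member be the active-site cluster. Counts over a threshold grid are monotone
non-increasing in every threshold. Conservation summaries and the pair scan
run only for families with at least 5 representatives; smaller families are
still clustered, with the exclusion logged.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| grid spacing | 1.0 | Å | detector resolution; center error ≤ one spacing |
| probe + atom radius | 1.6 + 1.7 | Å | protein-mask reach around each Cα |
| PSP minimum | 5 of 7 | directions | burial required of a pocket point |
| min pocket points | 30 | grid points | suppresses spurious micro-cavities |
| residue radius | 8.0 | Å | pocket residue assignment (closed bound) |
| base threshold | 2.0 | Å | clustering net before adding `avg_rmsd` |
| identity threshold | 0.95 | fraction | representative grouping |
| α | 0.05 | — | all significance calls (p ≤ α) |
| min representatives | 5 | structures | floor for conservation analyses |
| pair distance | 8.0 | Å | minimum centroid separation of a pair |

The detector defaults were chosen so globular fixtures yield on the order of
5–10 pockets per structure, the regime the clustering stages are designed
for. All are configurable per run.

## What the synthetic generators emulate — and what they do not

`gen_family()` emits noisy copies of a helical Cα scaffold (3.8 Å consecutive
spacing) with planted pocket clusters (known centers, per-structure presence
probabilities, size distributions, jitter), optional decoy scatter, random
per-member rigid motions, and mutated copies of a base sequence that double
as a gap-free alignment with planted conserved columns. `gen_hollow_shell()`
builds closed cavities with known centers for detector geometry;
`gen_flex()` plants rigid/flexible B-factor patches of known effect size.
Every generator is a pure function of its seed, and fixtures round-trip
through the package's own PDB/FASTA/TSV writers.

These fixtures validate the *machinery*: partition correctness, coverage
recovery within binomial bounds, test calibration and power, detector
geometry, threshold semantics, determinism. They do not contain real
side-chain packing, ligands, indel-rich alignments, domain motions or
crystallographic artifacts — so green tests certify the implementation, not
the biological performance of the method on real families, which depends on
dataset-scale inputs this package deliberately does not download.

Test and acceptance problem sizes (families of 6–20 structures of 40–60
residues, cohorts of up to 20 families, 2,000-draw null simulations,
100-seed power runs) were chosen as the package's standard verification
scale; all scale linearly if larger runs are wanted.

## Numerical choices

- Sample (n−1) standard deviations everywhere a SD normalizes a profile.
- All significance boundaries are closed (p ≤ 0.05), as are the 8 Å residue
  and pair-distance rules and the clustering threshold itself.
- Greedy score ties break on ascending pocket id; ranking ties on coverage,
  then founder id; reference ties on resolution, then id — every stage is
  deterministic given its inputs.
- Kabsch rotations are proper (determinant +1, reflection-corrected);
  collinear or sub-3-point correspondences raise degenerate-fit errors
  instead of returning garbage.
- Constant B factors or constant conservation scores yield flat profiles
  with a warning (normalization) or p = 1 (tests), never exceptions.
- Screened-Coulomb distances are floored at 1 Å to keep the point-charge
  model finite near a charge.
- A structure aligning to fewer than half of its residues triggers a
  low-coverage warning on conservation mapping.

## Known limitations

- The detector sees only the Cα trace with a uniform atom radius; pocket
  sizes are grid-point counts, proportional to volume only at fixed spacing.
- Superposition requires alignable sequences; it is not a substitute for
  sequence-independent structure alignment across remote homologs.
- The electrostatic model ignores protonation, dielectric boundaries and
  ionic-strength detail; use it comparatively, not quantitatively.
- Per-structure B′ normalization means a chain's mean flexibility is zero by
  construction; cross-structure flexibility comparisons need a shared
  normalization unit, which is out of scope here.
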
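# pocketconserve

Structural conservation of ligand-binding pockets across protein families.

Many functional sites — catalytic pockets, effector sites, allosteric sites —
persist at the same spatial position across the solved structures of a
protein family even when their residues drift in sequence. `pocketconserve`
measures that persistence. Given a family of structures it detects putative
ligand-binding pockets, superimposes the family's representative structures
onto a common reference, clusters pocket centers that occupy equivalent
positions, and scores each cluster by how much of the family carries it. The
package is aimed at structural bioinformaticians screening families for
conserved-but-sequence-silent pockets (allosteric candidates) and at anyone
who needs a reproducible, scriptable pocket-conservation pipeline.

## The method in brief

- **Pocket detection.** A LIGSITE-style protein–solvent–protein (PSP) grid
  scan: solvent grid points enclosed by protein along ≥ 5 of 7 scan
  directions are pocket points; 26-connected components become pockets,
  each summarized by its center of mass and size, with member residues
  within 8 Å of the center. Pre-computed pocket tables are accepted too.
- **Superposition.** Kabsch least-squares fits of each representative onto
  the reference over sequence-corresponded Cα atoms; the family's average
  RMSD measures its structural fluctuation.
- **Family clustering.** Greedy, size-weighted clustering of pocket centers
  with the family-specific threshold *2.0 Å + average RMSD*: each element is
  scored by the summed sizes of its neighbors, the best founds a cluster of
  all its neighbors, members leave the pool, and scores are recomputed until
  the pool is empty.
- **Scoring.** For a cluster *c* with members of size *size_i* drawn from
  *n_r* of the family's *m* representatives:

  ```
  Str_c   = 100 · n_r / m                    (structural conservation, %)
  Score_c = (Σ size_i / n_c) · Str_c         (ranking score)
  ```

- **Characterization.** Per-pocket one-sided Wilcoxon–Mann–Whitney tests at
  p ≤ 0.05 for sequence conservation (Henikoff-weighted, SD-normalized
  inverted column entropies from the family alignment) and for flexibility
  (z-scored B factors, `B′ = (B − ⟨B⟩)/σ(B)`; NMR ensembles via
  `B = 8π²/3 · RMSF²`), plus a screened-Coulomb potential at the pocket
  center (sign/magnitude comparisons only).
- **Allosteric scan.** Pairs of clusters that are both structurally
  conserved (Str_c ≥ 50% by default) and ≥ 8 Å apart (centroid distance)
  are reported as candidate functional/allosteric site pairs, optionally
  requiring sequence conservation or an active-site member.

Active-site annotations (1–3 residues per structure) map to the pocket
holding the majority of them; the cluster with the most mapped pockets is
the family's active-site cluster, and a threshold benchmark reports
recall/contamination of that cluster over a sweep of base distances.

## Worked example

Everything below is synthetic and self-contained — the package ships
generators that plant pocket clusters, conserved alignment columns and
active-site annotations with known ground truth:

```r
library(pocketconserve)

fam <- gen_family(
  seed = 11, m = 8, n_res = 60, noise_sigma = 0.5,
  clusters = list(planted_cluster(c(0, 0, 20)),                  # active site
                  planted_cluster(c(0, 0, 75), presence = 0.75)), # distal pocket
  conserved_residues = which(colSums((t(gen_scaffold(60)) - c(0, 0, 20))^2) <= 64),
  active_site_cluster = 1)
paths <- write_family_fixture(fam, "readme_fam")

res <- run_family_analysis(run_config(
  input_dir = "readme_fam", out_dir = "readme_out", family_id = "DEMO",
  msa_path = paths$msa, annotations_path = paths$annotations,
  pockets_path = paths$pockets, seed = 1))
```

`readme_out/summary.txt` then reads:

```
family: DEMO
seed: 1
parameters: base_threshold=2.00 residue_radius=8.00 alpha=0.05 identity=0.95 min_representatives=5 pair_min_distance=8.00 str_threshold=50.0
representatives: 8 of 8 members (reference S01)
avg_rmsd: 1.166 A; clustering threshold: 3.166 A
pockets: 13 in 2 clusters
active-site cluster: 1
qualifying cluster pairs: 1
cluster 1 (active site): n_c=8 str_c=100.0% score=10162.5 seq_conserved=100.0% flexible=12.5% rigid=12.5%
cluster 2: n_c=5 str_c=62.5% score=6100.0 seq_conserved=0.0% flexible=0.0% rigid=0.0%
```

Reading the numbers: the eight structures were superimposed with an average
RMSD of 1.166 Å, so pockets were clustered with a 3.166 Å family threshold.
The planted active-site pocket appears in every representative
(`str_c = 100%`), is the top-ranked cluster, carries the annotated active
site, and every one of its member pockets is significantly conserved in
sequence. The distal pocket was planted with 75% presence and is recovered
at 62.5% coverage (5 of 8 structures) with no sequence-conservation signal —
and because the two cluster centroids are 55.2 Å apart, they are reported as
one qualifying conserved-and-distant pair:

```r
res$pairs[, c("cluster_a", "cluster_b", "centroid_distance", "str_a", "str_b")]
#>   cluster_a cluster_b centroid_distance str_a str_b
#> 1         1         2          55.19484   100  62.5
```

Each stage also writes its own TSV/JSON table under `readme_out/`
(`family_manifest.tsv`, `transforms.json`, `pockets.tsv`, `clusters.tsv`,
`pocket_reports.tsv`, `cluster_summaries.tsv`, `active_site_map.tsv`,
`pairs.tsv`, `strc_histogram.tsv`).

A thin command-line wrapper covers the same flow:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "pocketconserve", package = "pocketconserve"))')
Rscript "$CLI" simulate --out fam --seed 4 --m 6
Rscript "$CLI" run --input fam --msa fam/family.afa \
    --annotations fam/active_sites.tsv --pockets fam/pockets.tsv --out out
```

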
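# panedit

Quantitative analysis of uridine-insertion mRNA editing and its effect on
protein hydrophobicity.

Kinetoplastid mitochondria (e.g. *Trypanosoma*, *Leishmania*) edit many of
their mRNAs by inserting — and occasionally deleting — uridines at sites
specified by guide RNAs. In *pan-edited* genes most of the coding sequence
is created by inserted Us. Because any codon with U at its second position
encodes a hydrophobic amino acid, this editing systematically pushes the
encoded proteins toward extreme hydrophobicity. `panedit` provides the
statistics and sequence/structure tooling needed to study that process,
for molecular evolutionists working on kinetoplastids and related
Euglenozoa.

## What the package computes

* **Nucleotide walks.** The cumulative statistic
  `s[U_k] = Σ_{i=1..k} x[i]`, with `x[i] = +1` when position *i* carries a
  U and `−1` otherwise, overall or restricted to one codon position: a
  positive slope marks local U enrichment.
* **Codon-position composition tests.** U content per codon position with
  windowed (30-base, non-overlapping) standard deviations; a χ²
  goodness-of-fit test (df = 2) of homogeneous U distribution across codon
  positions, where expected counts are proportional to per-position site
  totals (for df = 2 the p-value has the closed form `exp(−χ²/2)`); and an
  uncorrected 2×2 χ² comparison of U proportions between species.
* **Inserted-U inference.** An anchored alignment of a cryptogene to its
  fully edited mRNA: the shared non-U characters are matched one-to-one
  and each inter-anchor U run yields an insertion or deletion count.
  Inserted Us are assigned codon positions under an explicit placement
  convention (`genomic_left`, with `genomic_right` for sensitivity), and
  their homogeneity across codon positions is tested.
* **Hydropathy profiling.** Cumulative Kyte–Doolittle profiles on mRNA
  coordinates, hydrophobic fractions (set F, L, I, V, M, W, Y),
  order-/disorder-promoting composition tables, and ranking of a query
  protein within a survey set.
* **Hydrophobic cluster analysis.** Residues placed on a duplicated
  alpha-helical net (3.6 residues/turn); hydrophobic clusters delimited by
  a sequence-separation rule (≤ 4) with proline breaks; SVG plots with the
  conventional symbols.
* **Structure analysis.** Shrake–Rupley solvent-accessible surface area
  (probe 1.4 Å, 960 sphere points, element radii C 1.70 / N 1.55 / O 1.52
  / S 1.80 Å), relative SASA against theoretical per-residue maxima,
  exposure at a strict 30 % cutoff, interface detection by SASA reduction
  upon complex formation, and site-wise hydrophobicity-increase
  comparisons between aligned homologs with 2×2 χ² tests by stratum.
* **Coevolution summaries.** Counting short-range (≤ 5 residues apart)
  site pairs above a score threshold in a user-supplied coevolution
  matrix, and the fraction of such pairs that are hydrophobic–hydrophobic.
* **Synthetic data.** Seeded generators of cryptogene/edited-mRNA pairs
  with recorded editing events, diverged species sets with a purifying
  factor on the second codon position, and toy two-chain complexes with
  known contact sets — so the whole pipeline is testable without
  downloads.

## Worked example

Simulate a pan-edited gene, re-infer its editing events, and watch
hydrophobicity emerge:

```r
library(panedit)

sim <- simulate_editing_pair(editing_sim_params(seed = 1))
aln <- anchor_align(sim$cryptogene, sim$edited)
aln
#> <editing_alignment> sim00000001_crypto -> sim00000001_edited: 404 anchors, 436 inserted U, 1 deleted U

ins <- inserted_by_codon_position(aln)
ins
#> [1] 150 137 149
inserted_homogeneity_test(ins)
#> <test_result> inserted-U homogeneity across codon positions: X-squared = 0.7202, df = 2, p = 0.6976

u_content_by_position(sim$cryptogene)
#> <position_counts> U: 16/150  12/150  18/150 (0.107 0.080 0.120)
u_content_by_position(sim$edited)
#> <position_counts> U: 164/295  152/295  165/295 (0.556 0.515 0.559)

hydrophobic_fraction(translate_cds(sim$edited, allow_internal_stops = TRUE))
#> [1] 0.6474576
hydrophobic_fraction(translate_cds(sim$cryptogene, allow_internal_stops = TRUE))
#> [1] 0.1208054
```

Editing inserts Us with no codon-position preference (p ≈ 0.70 for the
homogeneity test), raises the U content from about 0.10 to about 0.54 at
every codon position, and more than quintuples the hydrophobic fraction of
the encoded protein — the sequence-level signature the package is built to
measure. Real pan-edited mitochondrial proteins sit at comparable
hydrophobic fractions (≈ 0.6–0.7) against a eukaryote-wide background near
0.5.

The same operations run from the shell via the thin wrapper in
`inst/cli/panedit.R`:

```sh
Rscript inst/cli/panedit.R composition --config run.yaml --out results/
```

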
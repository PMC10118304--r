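---
title: "Methods: measuring how U-insertion editing drives protein hydrophobicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring how U-insertion editing drives protein hydrophobicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panedit)
```

## The scientific setting

Kinetoplastid mitochondria post-transcriptionally insert (and more rarely
delete) uridines in many mRNAs. In pan-edited genes the mature coding
sequence is largely built from inserted Us. The genetic code guarantees
that a U in the second codon position yields a hydrophobic amino acid, so
extensive U insertion mechanically drags the encoded protein toward high
hydrophobicity. `panedit` packages the descriptive statistics and tests
used to characterise this process at three levels: the mRNA (walks and
codon-position composition), the protein sequence (hydropathy, cluster
analysis, composition classes), and the protein structure (solvent
accessibility, interfaces, homolog comparisons).

## Nucleotide walks and composition tests

The walk statistic adds +1 at each target base (U by default) and −1 at
any other base, cumulatively along the sequence or along the sites of one
codon position. The final value is therefore `2·#U − n` over the `n` sites
walked, and the per-position finals sum to the unrestricted final — two
invariants the test suite checks on thousands of random sequences. `N`
bases step −1 like any non-target base, which keeps the unit-step
invariant exact; they count as sites but never as U in composition tables.

Codon positions are indexed from `frame_offset + 1`; a trailing partial
codon is truncated with a warning. All user-facing coordinates are
1-based.

The homogeneity test is a χ² goodness of fit of the three per-position U
counts against expectations proportional to per-position site totals
(identical to equal thirds when the span is a multiple of three, robust
otherwise), on 2 degrees of freedom. For df = 2 the p-value equals
`exp(−χ²/2)`, which the test suite uses as an independent closed-form
oracle at 1e−10 tolerance. The between-species comparison is an
uncorrected 2×2 χ² on whole-CDS U vs non-U counts; no continuity
correction and no multiple-testing adjustment are applied, because the
reporting convention this reproduces uses raw per-gene significance
stars. Raw counts (not proportions rescaled to a common length) enter the
2×2 table. Windowed variability uses non-overlapping 30-base windows
(trailing remainder dropped, warned) and the population standard
deviation of per-window U proportions — the two-window half-U/half-A case
gives SD 0.5, which pins down the population (not sample) convention.

## Inferring inserted Us

U-indel editing leaves the non-U characters of cryptogene and edited mRNA
identical and in order. The aligner exploits this: non-U characters are
matched 1:1 as anchors, and each inter-anchor U run is compared. A run
contributes `max(edited_U − crypto_U, 0)` insertions or the mirror-image
deletions — never both, by construction. Pairs whose non-U skeletons
differ are rejected with the first mismatch position in both coordinate
systems, since such pairs cannot be explained by U editing alone.

Which U slots within a run are "the inserted ones" is not identifiable
from sequence: only the run totals are. The package therefore makes the
placement convention explicit. Under the default `genomic_left`, genomic
Us occupy the 5′-most slots of each run; `genomic_right` is computed as a
sensitivity check, and the per-gene report carries both. The two
conventions can differ by at most the number of runs containing both
genomic and inserted Us. The synthetic generator writes its ground truth
in the `genomic_left` convention, which is what makes exact round-trip
recovery assertable in tests; cross-convention agreement is reported, not
asserted.

Only the CDS is analysed; insertions landing beyond the last complete
codon of the edited frame are not assigned a codon position.

## Protein-level analyses

Hydropathy uses the standard Kyte–Doolittle table; `X` contributes 0.
Cumulative profiles carry an mRNA coordinate per residue (first base of
the codon) so they can be overlaid on nucleotide walks. The hydrophobic
set is F, L, I, V, M, W, Y throughout; C is treated as order-promoting
but not hydrophobic. The default order/disorder map is order
{W, C, F, I, Y, V, L, N}, disorder {A, R, G, Q, S, P, E, K}, ambiguous
{D, H, M, T}; it is a configurable argument because the literature offers
several closely related classifications.

Translation defaults to genetic code table 4 (mold/protozoan
mitochondrial), in which UGA is tryptophan, as in kinetoplastid
mitochondria; the table id is configurable. Codons containing `N`
translate to `X`; a terminal stop is dropped; internal stops are an error
unless explicitly allowed (then `X`), because an internal stop in a
supposedly complete CDS usually indicates a frame or trimming problem.

Survey ranking uses dense descending ranks with ties sharing a rank, and
reports the sample mean and SD of the hydrophobic fractions.

Coevolution matrices are inputs, not computed. The pair summary counts
unordered pairs with sequence separation `j − i ≤ 5` (inclusive) and
score strictly `> 0.8` by default. Both the strictness of the threshold
and the inclusivity of the distance are assumptions — the conventions
they mirror do not specify them — so both are exposed as parameters, and
an all-pairs brute-force loop serves as the oracle in tests.

## Hydrophobic cluster analysis

Residues are placed on a duplicated alpha-helical net: x is the sequence
index and y the helical phase at 3.6 residues per turn, with a second
copy one full turn above so clusters that wrap the helix remain
contiguous. The published visual tools do not document their exact
connectivity shapes, so the package adopts a transparent approximation:
two hydrophobic residues join the same cluster when their sequence
separation is at most 4 and no proline lies strictly between them.
Both the gap (`max_gap`) and the breaker set (`breakers = "P"`) are
parameters. Hydrophilic gaps are reported as maximal runs of ≥ 4
non-hydrophobic residues. Judgements like "substitutions fall at cluster
edges" are left to the user: the package reports distances from annotated
sites to cluster boundaries rather than a verdict.

## Structure analyses

SASA is computed with an in-package Shrake–Rupley implementation: each
atom's extended sphere (van der Waals radius + 1.4 Å probe) is sampled
with 960 evenly distributed (Fibonacci spiral) points, and a point is
accessible when outside every other atom's extended sphere. Element radii
default to C 1.70, N 1.55, O 1.52, S 1.80 Å; hydrogens are ignored;
unknown elements fall back to a configurable default with a warning. The
implementation is validated against closed forms: an isolated sphere
(within 1 % at 960 points) and the two-sphere spherical-cap formula
`4πR² − 2πR(R − d/2)` (within 2 %); the error decreases with more
points.

Relative SASA divides by theoretical per-residue maxima (Tien et al.
2013). The choice of normalisation table shifts exposure counts, which is
why the table is exported (`MAX_ASA`) and replaceable. Exposure is a
strict `> 0.30` on relative SASA — exactly 30 % is not exposed.

Interface residues are those whose SASA drops when the partner chain is
present. "Any reduction" is operationalised as `ΔSASA > 0.1 Å²`: a strict
`> 0` would flip flags between runs with different point counts, because
point sampling leaves residue-level differences of order 0.01 Å² even far
from any contact.

Homolog site pairing is an input: curated alignments should be supplied
as two-column index pairs. A helper global aligner (BLOSUM62, gap open
11 / extend 1) is provided for synthetic tests. "Hydrophobicity increase"
at an aligned site is a strict Kyte–Doolittle comparison
`KD(query) > KD(subject)`; gapped sites are excluded (how they should be
counted is genuinely ambiguous, and excluding them is the conservative
choice). Stratum comparisons (exposed/buried, interface/non-interface,
edited/unedited) reuse the uncorrected 2×2 χ² machinery; empty or
degenerate strata produce a warning and a skipped test rather than an
arbitrary statistic.

## The synthetic-data generators

`simulate_editing_pair()` emulates the editing-relevant statistical
structure of a pan-edited gene. The default cryptogene is 150 codons of
composition A 0.30, C 0.15, G 0.45, U 0.10 — U-poor and G-rich, as
cryptogenes are. Each anchor gap receives a geometric run of inserted Us
(mean length 2, matching the observation that editing inserts several Us
at contiguous or close positions) with an expected 1.1 insertions per
gap, so that the edited mRNA ends up slightly above 50 % U with roughly
90 % of its Us inserted — the regime reported for pan-edited genes, where
inserted/total U ratios are around 0.9. Deletions hit genomic Us at rate
0.05, only in runs without insertions, keeping each run purely insertion
or deletion as the anchored model requires.

With `position_bias` set, the generator instead draws the edited mRNA
directly with per-site U probabilities proportional to the bias at each
codon position and removes every U to form the cryptogene — a fully
pan-edited pair. This is the one regime in which a codon-position
preference of insertions is cleanly identifiable (when runs mix genomic
and inserted Us, within-run placement is unidentifiable and would dilute
any bias), and it is how the bias-recovery check at ≥ 5,000 insertions is
run.

`simulate_divergence()` applies independent per-site substitutions at
per-codon-position rates, dividing the second-position rate by a
purifying factor (default 10, 20 species, rate 0.1/site) — the mechanism
behind the observation that second-position U content stays least
variable across species that lost editing. It is deliberately not a
phylogenetic simulator: species are independent draws from the root, with
no tree, no rate heterogeneity beyond codon position, and no
amino-acid-level selection.

`make_toy_complex()` builds two idealized poly-alanine traces (one
interaction sphere per residue): a contact block at 3 Å between chains,
with the rest of the second chain walking away perpendicular to the
first. The geometry quantizes cross-chain distances away from the
occlusion cutoff `r_i + r_j + 2·probe` (the construction asserts no pair
falls within 0.3 Å of it), so the recorded ground-truth contact set is
unambiguous and interface recovery can be asserted as set equality.

What the generators do **not** emulate: guide-RNA anchoring and 3′→5′
editing polarity, partially edited intermediates, codon-usage selection,
phylogenetic covariance, or realistic side-chain packing. Passing tests
therefore demonstrate that the statistics are computed correctly and that
the inference is exact under the stated identifiability conventions — not
that real GenBank-derived data would yield any particular value.

## Problem sizes and reproducibility

The test suite and acceptance script use: 1,000 simulated editing pairs
of 150 codons for round-trip recovery; 10,000 random sequences for walk
conservation; a 3,500-codon pan-edited pair (≈ 5,700 insertions) for bias
recovery; a 9,999-base root with 20 species for the divergence contrast;
and toy complexes of 15–40 residues per chain at 960 SASA points. These
sizes give binomial/Poisson sampling errors comfortably below the
assertion margins while keeping a full run in the tens of seconds. Every
stochastic routine takes an explicit seed, and the pipeline writes a
manifest (inputs, parameters, package version, seed) alongside
fixed-format (6-decimal) TSV outputs so reruns are byte-identical.

## Known limitations

* Within-run placement of genomic vs inserted Us is unidentifiable;
  results that depend on it are reported under both conventions.
* Relative-SASA-dependent counts shift with the max-ASA reference table.
* The HCA connectivity rule is an explicit approximation of a visual
  tool; cluster boundaries within one residue of a gap threshold are
  sensitive to `max_gap`.
* Analyses that require external inputs — large survey sets, deposited
  complex structures (e.g. respiratory complex I), coevolution matrices —
  operate on whatever the user supplies; the package validates and
  processes them but cannot vouch for their provenance.
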
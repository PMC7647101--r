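---
title: "Differential amino-acid usage in anchored peptide sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential amino-acid usage in anchored peptide sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdau)
```

## The problem

Sets of peptides that share a biological anchor — a protease cleavage site,
a phosphorylated Ser/Thr, a mature N-terminus — carry positional sequence
preferences that reflect the specificity of the enzyme or pathway that
produced them. Information-content logos show what is *common* in such a
set, but they answer the wrong question when the interesting signal is a
*difference* from what the proteome would yield anyway: a residue can be
frequent at a position simply because it is frequent everywhere. `pepdau`
instead tests, cell by cell (position × symbol), whether the input set's
usage differs from a background model built from the proteome under
constraints that match the experiment, and draws only the significant
differences.

## Data model

- A **proteome** is a tibble of full-length protein sequences. Non-standard
  residues (`U`, `B`, `Z`, `*`) are retained on ingestion — dropping whole
  proteins would bias backgrounds — but are non-countable everywhere, like
  padding.
- A **peptide set** holds equal-length windows of `L = upstream + 1 +
  downstream` columns around the anchor. Columns beyond a protein's termini
  are padded with `X`; `X` may only appear as a contiguous prefix/suffix,
  and the anchor column must hold a standard residue (an anchor must be
  testable). Unaligned input is accepted in the anchored syntaxes
  (`"ASTRSkSSTD"`, `"ASTRSK*SSTD"`, or positional tokens such as `"K123"`)
  and windowed by the package; pre-aligned input goes through
  `format_aligned()`.
- A **grouping scheme** is a total partition of the 20 amino acids into
  groups with display symbols and colors. Built-ins: `identity`,
  `charge3` (+/0/−), `hydrophobicity3`, `size5`; `register_scheme()` and
  scheme JSON files add custom ones. One published grouping lists alanine
  twice and omits glutamine in the neutral hydrophobicity class; since a
  scheme must partition the alphabet, `hydrophobicity3` places Q in the
  neutral group. Schemes based on continuous property indices (pI,
  polarity, bulkiness, volume, substitutability) are supported as custom
  schemes rather than shipped with fixed memberships, because no canonical
  group definitions exist for them.

## Background models

Twelve configurations combine the proteome-level space (`wholeProteome`,
`inputSet`, `nonInputSet`) with the positional space (`nterm`, `cterm`,
`anywhere`, the latter optionally anchored on a residue set). The choice
matters: an N-terminal acetylation study should sample protein N-termini,
a lysine-modification study should anchor the background on lysines.

**Z mode** bootstraps `T` background sets of `N` windows each and records,
per cell, the mean frequency `p̄ = Σ_t p_t / T` and its binomial standard
error `s̄ = sqrt(p̄ (1 − p̄) / N)`. The SE uses `p(1−p)/N`, the correct
variance of a proportion estimated from `N` sequences (an earlier tool
lineage used `p/N`). Defaults are `T = 300` and `N =` the input-set size —
with `N` equal to the input size, `s̄` also approximates the sampling error
of the input frequency itself, which is what makes the single-sample Z
statistic `Z = (p − p̄)/s̄` approximately standard normal under the null
(the type-I calibration test below verifies this empirically).

**Fisher mode** stores a single exhaustive background set as counts. For
`anywhere` spaces the pool is every residue position; it is capped at
`max_windows` (default 2 × 10⁵) with a seeded subsample beyond that, since
a mammalian proteome has ~10⁷ windows and the exact test gains nothing
beyond 10⁵ background sequences.

Sampling decisions: across bootstrap sets sampling is independent (with
replacement); within a set, windows are drawn without replacement whenever
the pool allows, else with replacement and a warning. Draws on the
`anywhere` space are uniform over residues, so longer proteins contribute
proportionally. All sampling flows from one seed recorded in the model, and
models serialize losslessly to JSON.

Collapsing to a reduced alphabet happens **before** frequency computation,
so group counts are exactly the sums of member counts (an invariant the
tests assert).

## The tests

Per cell, `diff = p − p̄` (input minus background frequency).

- **Z-test**: `Z = diff / s̄`, two-sided normal p-value. Degenerate cells
  (`s̄ = 0`, `p ≠ p̄`) get `Z = ±Inf`, `p = 0`, and a note; columns with no
  countable input residues stay in the result grid as `NA` cells rather
  than disappearing.
- **Fisher's exact test**: the 2×2 table `[[a, b], [c, d]]` of symbol
  presence/absence in input vs background at the position. The two-sided
  p-value follows the point-probability convention — the sum of
  probabilities of all tables with the observed margins whose point
  probability does not exceed the observed one, with the same `1 + 1e-7`
  relative guard `stats::fisher.test()` uses; two-sided conventions differ
  between implementations, so this one is stated explicitly and checked
  exhaustively against an independent enumeration oracle. The reported
  statistic is the raw sample odds ratio.

No multiple-testing adjustment is applied by default: each cell is tested
at its stated level, which matches how such analyses are conventionally
read. Benjamini–Hochberg across cells is available (`adjust = "BH"`) for
users who want family-wise rigor. The anchor column is tested like any
other column — with a Ser/Thr-anchored set its composition is informative
(relative Ser vs Thr usage), not trivial.

## Visualization

The logo draws only significant cells: over-represented symbols stacked
above the axis, under-represented below, glyph height the percentage-point
frequency difference `|diff| × 100` with the largest glyph nearest the
axis (a `-log10 p` height is available behind a flag). Glyphs are colored
tiles carrying the symbol letter — a device-independent rendering whose
geometry is testable directly from the plot data. Heatmaps show the full
L × K grid of Z-scores (or differences) on a diverging scale centered at
zero, with `NA` cells in grey. Column labels default to offsets
(−upstream … 0 … +downstream); a protease mode prints P15…P1, P1′…P15′,
with the anchor at P1 and P1′ the first position C-terminal of the
scissile bond. Output formats: SVG (reference), PNG, PDF.

## The synthetic-data generator

`synth_proteome()` draws i.i.d. residues (uniform by default; a
human-proteome-like composition is provided) with lengths uniform on a
range; `plant_motif_peptides()` synthesizes windows whose columns follow
stated per-position target frequencies, the remaining mass shared among
unspecified residues in proportion to the baseline, and returns the truth
table of planted effects; `null_peptides()` draws windows exactly as the
anywhere-unanchored background sampler does. Fixtures are written as
FASTA + TSV so tests exercise the real I/O paths.

What the generator emulates: known per-position frequency structure over
an i.i.d. proteome, X-padding at termini, anchored windows. What it does
not: residue autocorrelation along real proteins, compositional biases of
protein families, experimental-protocol artifacts, or inter-site
dependence within a motif. Passing the recovery and calibration tests
therefore demonstrates that the statistics behave as designed under their
own assumptions — not that a particular biological claim is true of real
data.

## Study sizes and numerical choices in the test-suite

The suite's study conditions mirror the method's canonical use: a
protease-substrate-style recovery study (n = 416 windows of L = 30,
aspartate planted at the anchor at frequency 0.8 against a 0.05 baseline,
background `T = 300`, `N = 416`), a type-I calibration (n = 400, L = 15,
uniform baseline, 20 seeded replicates, the fraction of cells with
p < 0.05 required inside the 99% binomial band around 0.05), and an
exhaustive Fisher-vs-enumeration sweep over all 2×2 tables with both
margins ≤ 30. The synthetic proteome holds 500 proteins of 100–300
residues (~10⁵ residues), large enough that bootstrap error, not proteome
granularity, dominates background uncertainty.

For the Z-vs-Fisher concordance study the fixture is group-level
(`charge3`, L = 15, n = 400) with charge-group targets growing smoothly
along the window. The design is deliberate: rank agreement between an
exact test and its normal approximation is only meaningful where cells
differ in true effect. At the single-residue level a fixture necessarily
contains families of cells with identical planted targets; their observed
counts tie, and within such tie blocks the two tests order p-values by
independent background noise, which caps the rank correlation — and in the
deep left tail (counts near zero) the normal approximation genuinely
diverges from the exact test, the known weakness of Z-tests on small
counts. With group-level cells the counts are large, every cell has a
distinct effect, and the two tests agree in sign everywhere with Spearman
ρ ≈ 0.99.

Other numerical conventions: frequencies sum to 1 per position within
1e-9 over countable symbols; ties in the logo stacking order break by the
result-table order (stable); `sample()`'s hash algorithm is used for large
without-replacement draws, so draws depend only on the seed; equality
checks on serialized artifacts are byte-level.

## Known limitations

- The Z-test ignores the input set's own sampling variance except through
  the `N = input size` convention; for very small input sets use Fisher
  mode (the exact test is also the better choice when background pools are
  small).
- Backgrounds are scheme-specific by construction; a background built under
  one alphabet cannot test another (the mismatch is an error, not a
  silent recompute).
- Live retrieval of proteomes from UniProt/Biomart is out of scope: inputs
  are local FASTA files.
- The logo is a block-style rendering (colored tiles with letters), not
  scaled letter outlines; heights, order, and sign carry the same
  information.
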
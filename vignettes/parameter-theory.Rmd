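---
title: "Choosing sum-of-pairs alignment parameters from family statistics"
author: "msaparam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing sum-of-pairs alignment parameters from family statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaparam)
```

## The problem

Progressive multiple sequence aligners optimise a sum-of-pairs (SP)
objective

$$\mathrm{score} = \sum \mathrm{Residue} - \sum \mathrm{penalty},$$

where the residue term sums a substitution-matrix score over every column
and every pair of rows, and the penalty term charges an affine cost for
gaps: GOP for opening a run of gaps, GEP for each extension, so a run of
length $R$ costs $\mathrm{GOP} + (R-1)\,\mathrm{GEP}$. Alignment quality is
notoriously sensitive to the choice of matrix, GOP and GEP, and most users
run the defaults. This package implements a closed-form theory that chooses
these parameters from statistics of the *unaligned* family itself, plus
everything needed to exercise the theory end to end: format I/O, an SP
scorer and the SPS benchmark metric, a small progressive Gotoh aligner, a
synthetic family simulator and a parameter-sweep harness.

## Family statistics

All formulas are parameterised by five quantities of the unaligned family
(`family_summary()`):

* $m$ — number of sequences;
* $\mathrm{len}_{max}, \mathrm{len}_{min}$ — longest and shortest sequence
  lengths (residues);
* $\mathrm{iden}$ — mean pairwise identity, the fraction of identical
  aligned positions divided by the shorter sequence length, averaged over
  all $m(m-1)/2$ pairs;
* $\mathrm{num\_match} = \tfrac{m(m-1)}{2}\,\mathrm{len}_{min}\,\mathrm{iden}$
  — expected matched residue-pair count;
* $\mathrm{num\_gap} = \lfloor 0.2\,\mathrm{len}_{max}\rfloor +
  \mathrm{len}_{max} - \mathrm{len}_{min}$ — a per-sequence bound on the
  gaps an alignment inserts, reflecting the empirical observation on
  curated benchmark alignments that the longest sequence rarely gains more
  than 20% of its length in gaps.

The rounding function in $\mathrm{num\_gap}$ is implemented as `floor`
(its arguments are non-negative, so this is plain truncation), which
reproduces the worked example: a 25-column alignment of a family with
$\mathrm{len}_{max}=21$, $\mathrm{len}_{min}=7$ inserts
$25-21=4$ gaps into the longest sequence (`gaps_inserted(25, 21)`), 18 into
the shortest, with gap ratio $(25-21)/21 \approx 0.19$ (`gap_ratio(25, 21)`).

Identity is not defined operationally by the theory, so the package fixes a
deterministic convention: each pair is globally aligned with the internal
defaults (BLOSUM62, GOP 10, GEP 1) and identical columns are counted. When
a benchmark publishes annotated identities, `family_summary(..., identity =)`
accepts them directly.

## Matrix statistics and the rationality test

A substitution matrix is reduced to two numbers (`matrix_means()`): the
arithmetic mean $\overline{S_{aa}}$ of its 20 standard diagonal entries and
the mean $\overline{S_{ab}}$ of its 190 distinct off-diagonal entries.
Ambiguity codes and the stop column are excluded. A matrix is *rational*
for a family (`check_matrix()`) when

$$\overline{S_{aa}} \;\ge\; \frac{\alpha m - 2\alpha - m}{(1-m)\,2\beta}
  \cdot \frac{\mathrm{num\_gap}}{\mathrm{num\_match}}
  \;+\; \frac{\overline{S_{ab}}}{\beta},$$

i.e. the family's worst admissible alignment still scores at least the
unaligned family. The right-hand side is evaluated exactly in this printed
form; no algebraic rearrangement is attempted, because the derivation that
produces it involves grouping choices that the final form supersedes.

## The GOP/GEP estimators

Writing $\lambda$ for the mean gap-run length (so a sequence's
$\mathrm{num\_gap}$ gaps form $\mathrm{num\_gap}/\lambda$ openings) and
fixing $\mathrm{GOP} = n\,\mathrm{GEP}$, the total penalty of the worst
admissible alignment is $\frac{n+\lambda-1}{n\lambda} m\,
\mathrm{num\_gap}\,\mathrm{GOP}$, and requiring that alignment to score at
least the unaligned family yields the upper bound (`gop_upper_bound()`)

$$\mathrm{GOP} \le \Big[\tfrac{(\alpha m - 2\alpha - m)(m-1)}{2}
  \mathrm{num\_gap}\,\overline{S_{ab}}
  + \mathrm{num\_match}\,(\beta\,\overline{S_{aa}} - \overline{S_{ab}})\Big]
  \cdot \frac{n\lambda}{m\,(n+\lambda-1)\,\mathrm{num\_gap}}.$$

The estimate (`estimate_gop_gep()`) scales the bound by a weight
$\omega \in (0,1)$ and derives the extension penalty:

$$\mathrm{GOP} = \omega \cdot \mathrm{bound}, \qquad
  \mathrm{GEP} = \mathrm{GOP}/n.$$

A non-positive bound (which arises for degenerate statistics, e.g. an
identity near zero or a matrix whose mean mismatch score is positive) is an
error carrying the evaluated terms, never a silent clamp: surfacing a
degenerate family is safer than inventing a penalty.

### Weight coefficients and presets

$\lambda = 3$, $\alpha = 0.2$ and $\beta = 0.9$ are calibrated constants
shared by all family classes; $\omega$ and $n$ depend on the family's size
and length class (`select_preset()`):

| sequences $m$ | $\mathrm{len}_{max}$ | $\omega$ | $n$ | matrix  |
|---------------|----------------------|----------|-----|---------|
| 4–5           | < 100                | 0.03     | 5   | BLOSUM45 |
| 4–5           | 100–300              | 0.05     | 5   | BLOSUM45 |
| 4–5           | > 300                | 0.08     | 10  | BLOSUM62 |
| 14–19         | any                  | 0.02     | 10  | BLOSUM45 |
| ≥ 20          | any                  | 0.02     | 10  | BLOSUM45 |

Counts of 2–3 and 6–13 are not calibrated; they map to the nearest
small-family rows and the result is flagged `extrapolated`. The length
classes are keyed on $\mathrm{len}_{max}$ (the length statistic every other
formula uses); boundaries 100 and 300 are closed on the middle band, as the
class labels read.

```{r preset-example, eval = FALSE}
st <- family_stats(m = 4, len_max = 150, len_min = 120, iden = 0.3)
select_preset(st)
estimate_gop_gep(st, load_blosum("blosum45"),
                 msa_weights(omega = 0.05, n = 5))
```

## Scoring: SP and SPS

`sp_score()` implements the objective exactly as defined: residue-gap and
gap-gap column pairs score zero (gaps are charged once, through the affine
penalty, never through the residue term); terminal gap runs are penalised
like internal ones, since the model makes no end-gap exception.
`count_gaps()` decomposes the gap characters into openings (maximal runs)
and extensions, so `n_gop + n_gep` always equals the number of `-`
characters.

`sps()` is reference-pair recall, the convention of curated-benchmark
scoring: every reference column contributes one countable pair per row pair
with two residues, and the score is the fraction of those pairs whose
residues also share a column in the test alignment. Gap-residue pairs in
the reference are not counted. `sps(x, x) = 1` for any alignment with at
least one residue pair.

## The built-in aligner

`pairwise_affine_align()` is a three-state (match / gap-in-first /
gap-in-second) Gotoh dynamic program, exact for the affine model above and
verified against exhaustive alignment enumeration in the test suite. Ties
prefer match, then a gap in the first input, then the second, making output
deterministic. `progressive_align()` merges profiles along a UPGMA guide
tree built on $1 - \mathrm{identity}$ distances (ties broken by the
lexicographically smallest pair of cluster labels), with "once a gap,
always a gap". Profile-profile column scores are expected residue scores
under the product of column frequencies with gaps contributing zero, summed
over all cross-row pairs, and gap penalties are scaled by the receiving
profile's row count — so every merge optimises the same sum-of-pairs
objective `sp_score()` measures. There is no iterative refinement: the
package's claims concern parameters, not aligner sophistication.

## The simulator and the harness

`simulate_family()` evolves a uniform random root sequence down a star
topology: each leaf independently substitutes each site with probability
$1-\sqrt{\mathrm{target\_iden}}$ (two leaves then agree at a site roughly
with probability $\mathrm{target\_iden}$), deletes or inserts with a total
per-site indel rate of 0.05 by default (split evenly; insertion lengths
$1+\mathrm{Geometric}(0.5)$, leaf-specific residues, hence never homologous
across leaves). The event history yields the true alignment, and the
realised identity is recorded. This emulates the size, identity band and
modest length spread of small curated benchmark families. It does *not*
emulate domain shuffling, long terminal extensions, hydrophobic-core
conservation structure or realistic indel hotspots — so passing tests show
internal consistency of the method on tree-generated families, not
performance on real protein superfamilies.

`param_grid()` enumerates the evaluation grid: GOP from 1 to 20 in steps of
1, GEP from 0 in steps of 0.2 strictly below GOP/2, crossed with
BLOSUM30/45/62 — exactly 1,590 combinations (530 per matrix). The endpoint
rule is deliberate: the exact GOP/2 endpoint is only attainable for even
GOP, and including it would give 1,620 combinations; keeping GEP strictly
below GOP/2 is the enumeration consistent with the documented grid size,
and the strictness tolerance is $10^{-9}$. `sweep_family()` runs any such
grid plus a `theory` row (this package's estimate) and a `default` row —
the package's own internal defaults GOP 10, GEP 1, BLOSUM62, a conventional
raw-BLOSUM setting, explicitly *not* any external program's default.

## Problem sizes and numerical choices

The test suite works at desk scale, chosen so the full suite runs in well
under a minute: exhaustive-enumeration checks of the pairwise DP cover all
string pairs up to length 3 over a two-letter alphabet plus randomized
pairs up to length 6 over four letters; the SP scorer is checked against a
naive reference on 100 random alignments; the closed-form estimators
against independently coded evaluations on 1,000 random statistic draws;
the matrix-rationality property on 50 simulated families spanning the
calibrated size classes; and the theory-versus-default comparison on 20
simulated families with $m \in \{4,5\}$, root lengths 80–150 and target
identities 0.2–0.6. All randomness flows from fixed seeds; the simulate →
estimate → align → score pipeline is bit-reproducible.

Degenerate inputs are errors with actionable messages rather than silent
repairs: zero identity (no `num_match`), equal-length families (no
`num_gap`) for the bound, non-positive bounds, unknown residue letters
(matrix lookups never fabricate scores), all-gap rows, ragged alignments.
`GOP < GEP` in the aligner is a warning, since the affine model presumes
`GOP > GEP` but the DP remains well defined.

## Known limitations

* The GOP/GEP estimates live on the scale of the raw matrix entries'
  *means*, and the theory was calibrated against production aligners whose
  internally rescaled matrices make a gap-open penalty of 1–3 a strong
  penalty. Applied to the built-in aligner, which scores with raw half-bit
  BLOSUM entries, those same values are weak: on simulated families the
  estimated parameters over-fragment alignments and their mean SPS trails
  the internal defaults (compare `bench_theory_vs_default()`'s two
  columns). The estimator, the presets and the comparison baseline are all
  implemented exactly as specified; the shortfall is a scale mismatch
  between the closed-form theory and raw-score alignment, and users
  targeting production aligners should treat the estimates as being on
  those tools' penalty scales.
* The rationality threshold is evaluated in its printed closed form, whose
  first term is dimensionless; it is extremely permissive for ordinary
  families (BLOSUM mean mismatch scores are negative), so failing it
  signals genuinely pathological statistics.
* Mean-based matrix statistics discard the heterogeneity of the matrix;
  two matrices with equal means are indistinguishable to the theory.
* The identity convention (global alignment under internal defaults)
  differs from benchmark-annotated identities by a few points; supply
  `identity =` when an authoritative value exists.
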
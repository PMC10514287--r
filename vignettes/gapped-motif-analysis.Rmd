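---
title: "Gapped motif analysis of targeting peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gapped motif analysis of targeting peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gappedmotifs)
```

## The problem

N-terminal targeting peptides — chloroplast transit peptides (cTP),
mitochondrial transit peptides (mTP) and signal peptides (SP) — encode a
protein's destination in a short, weakly conserved stretch of sequence.
Antimicrobial peptides (AMP) share some of their physicochemical character
(cationic, hydrophobic) and are often analyzed alongside them. None of these
classes carries a crisp consensus; what distinguishes them is the
*statistics* of short, possibly discontinuous residue patterns: which gapped
motifs occur, how often, where along the peptide, and how this differs
between taxa.

`gappedmotifs` implements that census as a reusable, tested pipeline:

1. **datasets** — read FASTA + metadata, cut presequences at annotated
   cleavage sites, filter (nonstandard residues, minimum length 10, a
   100-residue cap for AMPs, exact-duplicate removal) with a per-step
   removal ledger;
2. **motif engine** — enumerate all gapped motif shapes, match them with
   overlap semantics, and count every *observed* motif into a sparse
   motif-by-sequence matrix;
3. **frequency** — presence fractions, per-size reporting cutoffs, and
   within-sequence repeat statistics;
4. **positional** — start-density profiles on a length-scaled 0–100 axis
   with a rule-based region classifier;
5. **alphabets** — reduced physicochemical alphabets (7/8/10 groups) so the
   same machinery runs on grouped residues;
6. **taxon comparison** — Mann–Whitney U tests on per-sequence occurrence
   counts with Benjamini–Hochberg correction and exclusivity calls;
7. **synthetic data** — a generator with planted-motif ground truth that
   every stage is validated against.

## The motif model

A gapped motif is an ordered list of 2–5 specified residue classes separated
by fixed numbers of unspecified positions, written e.g. `S_S` (serine, any
residue, serine) or `[AVIL]__[AVIL][AVIL]` on a reduced alphabet. The shape
grammar is:

| size (k) | gaps per slot | shapes |
|---|---|---|
| 2 | 0–3 | 4 |
| 3 | 0–3 each | 16 |
| 4 | 0–2 each | 27 |
| 5 | none, or exactly one single-residue gap | 5 |

Fifty-two shapes in total, every one spanning at most 10 positions. Two
readings of the size-3/4 gap budget are possible (per slot or total); we use
the per-slot reading — it is the only one consistent with motifs such as
`L___L___L` (two three-residue gaps) and the span-10 `K__K__K__K` — and
expose the bound as an argument (`enumerate_shapes(k, max_gap = ...)`) for
sensitivity analysis.

Matching is exact set membership at each specified position; unspecified
positions match anything. **Overlapping occurrences count separately**: a
run of four leucines contains three `LL` occurrences. This is the standard
k-mer convention; it makes repeat counts of homopolymer runs obey the closed
form `L − span + 1`, which the tests verify against brute force.

Counting is *lazy*: motifs are instantiated from the sequences actually
observed, never from Cartesian products of the alphabet, so memory scales
with the data, not with 20^5 possibilities. Internally the whole dataset is
flattened into one character vector and each of the 52 shapes is matched
vectorized across all sequences at once; per-(motif, sequence) aggregation
goes through `data.table` and the result is a `Matrix::dgCMatrix`.

Coordinates are 1-based everywhere a user sees them.

## Frequencies, repeats, thresholds

The frequency of a motif in a set is the fraction of sequences containing it
at least once. Full tables are always computed and written; the per-size
reporting cutoffs (defaults: bigrams 0.25, trigrams 0.10, tetragrams and
pentagrams 0.05) affect only the "top motifs" view. The defaults are our
own presentation-layer choice — the analogous published figures used manual,
per-figure cutoffs that are not recoverable — and they are arguments, never
hard-coded.

The repeat analysis considers only motifs occurring at least twice in at
least one sequence (the same economy used in the original analyses) and
reports the maximum per-sequence occurrence count plus the fractions of
sequences with ≥2 and ≥3 occurrences.

## Positional profiles

Start positions are mapped to a scaled axis: an occurrence starting at
1-based position $s$ in a sequence of length $L$ maps to
$100\,(s - 0.5)/L$. The half-position offset keeps values strictly inside
(0, 100) and avoids edge artifacts at both ends; the scaling itself is the
standard "length scaled to 100" device. Profiles are plain histograms
(default 20 bins of width 5); no kernel smoothing is involved in any
decision.

Region calls formalize the qualitative annotations used in this literature
as a deterministic rule on the profile's thirds (first < 35, middle 35–70,
last ≥ 70): *N-terminus* (≥ 50% of mass below 10), *first-part* / *middle*
(≥ 60% in that third), *C-depleted* (< 5% in the last third), *C-enriched*
(last third ≥ 2× each other third), else *whole*. Calls with fewer than 20
occurrences are low-support and default to *whole*. All cutoffs are
arguments and the per-third masses are returned, so any alternative rule can
be re-derived from stored output. The one positional claim that has a sharp
operational form — "starts with MA" — is additionally computed as an exact
prefix test, not via the histogram.

## Reduced alphabets

`enc7`, `enc8` and `enc10` partition the 20 letters into physicochemical
groups:

* enc7: AVIL, STNQ, RHK, DE, FYW, CGP, M
* enc8: AVIL, ST, NQ, RHK, DE, FYW, CGP, M
* enc10: VIL, A, ST, NQ, R, HK, DE, FYW, CGP, M

The authoritative table behind the published groupings is in supplementary
material we do not reproduce; these groupings are reconstructed to be
consistent with every reduced-alphabet motif printed in the primary results
(e.g. `[AVIL][STNQ][STNQ]`, `[VIL]_R_[VIL]`, `[FYW][VIL][VIL]`,
`[AVIL][AVIL][CGP]`). Because group membership of a few residues (C, G, P,
M; D/E vs H) cannot be pinned down from printed motifs alone, a config-file
loader (`read_alphabet()`, one group per line) is provided as the escape
hatch; validation enforces the exact-partition invariant either way.

Recoding replaces each residue by a single internal group symbol (a
lowercase ASCII letter — printable and regex-safe), so the motif engine is
completely alphabet-agnostic; bracketed letter-set rendering happens only at
the reporting boundary. Projection monotonicity — a reduced motif is at
least as frequent as any full-alphabet motif mapping onto it — is asserted
property-style across all presets.

## Taxon comparison

Between two disjoint taxa (membership = exact match against the lineage
list), each motif observed in either group is tested with a two-sided
Mann–Whitney U on **per-sequence occurrence counts**, zeros included.
Counts, not presence flags, are the default observable: rank tests on 0/1
data collapse into a tie-dominated two-proportion comparison, while counts
retain resolution; a presence-mode matrix can be passed for the stricter
reading. The exact null distribution is used when both groups have at most
eight sequences, the tie-corrected normal approximation (with continuity
correction) otherwise; when ties make the exact distribution unavailable,
`wilcox.test`'s own fallback to the approximation applies.

Benjamini–Hochberg correction is applied within a *family* of tests,
default: all motifs sharing a size and gap shape within one pairwise
comparison, mirroring per-motif-type reporting; `family = "k"` and
`family = "global"` are available because the original family boundaries are
not stated. Taxon-specific calls require significance plus a minimum
presence fraction (default 0.1) in the enriched group; *exclusive* motifs
(fraction exactly 0 on one side, positive on the other) are flagged without
requiring the test, subject to the same fraction floor.

## The synthetic generator: what it emulates, what it does not

`generator_spec()` describes i.i.d.-background peptides with planted
structure; `preset_spec()` ships five named study conditions:

* **cTP-like** (lengths 20–100): serine-rich background (S 0.18, A 0.12,
  L 0.10, P 0.07), `SS` and `S_S` planted uniformly at 0.70 each, `MA`
  planted as a prefix at 0.80. The prefix motif is planted last so that,
  under later-wins collision semantics, the N-terminal identity dominates
  interior serine plants.
* **mTP-like** (15–80): R/L-rich background, `LR`/`L_R`/`R_L` at
  0.50/0.50/0.45, `AAA` at 0.15.
* **SP-like** (15–40): leucine concentrated in the scaled 35–70 window of
  the *background itself* (L 0.45 there vs 0.08 elsewhere), emulating the
  hydrophobic h-region, plus `LL`/`LLL` planted mid-sequence at 0.65/0.30.
* **AMP-like** (10–100): lysine-rich background, `KK` and `K___K` planted
  uniformly at 0.40/0.35.
* **two-taxon-demo** (20–50): two equal taxa; the Streptophyta-like group
  plants `SP` at 0.6 and `S_S` at 0.6, the Chlorophyta-like group plants
  `S_S` at 0.1 and draws **no proline at all**, making `SP` exclusive by
  construction.

Planted insertions overwrite residues in place (lengths stay exact); gap
positions keep their background letters; every insertion is recorded with
its position and re-verified after generation, so clobbered insertions are
known. These presets are *qualitative emulations* chosen to exercise each
analysis stage with unambiguous ground truth. They deliberately do **not**
reproduce real data's length distributions, inter-positional dependence
(real presequences are not i.i.d.), compositional gradients other than the
single SP window, or realistic taxon imbalance. Consequently, passing tests
demonstrate that the machinery measures what was planted — e.g. observed
presence fractions exceed realized planting fractions only by background
collision mass — not that any particular biological percentage is
reproduced. On a serine-rich background, `S_S` reaches ~95% presence at a
0.70 planting rate precisely because background collisions add mass; that
is expected behavior, stated here to prevent misreading synthetic
frequencies as biology.

## Statistical calibration

`two_group_study()` runs replicated two-group experiments in which the focal
motif's residues are excluded from a six-letter uniform background
(A, L, K, T, G, P; lengths 15–40; 100 sequences per group), so planting
rates equal presence rates and all pure-background motifs are genuine
decoys. The restricted alphabet is a simulation design choice: it keeps the
decoy family dense (~144 bigram motifs) at desk-scale sample sizes. The
acceptance test runs 200 replicate pairs: under the global null the pooled
significant-motif rate stays below α + 3·SE, and a motif planted at 0.6 vs
0.1 is detected in ≥ 95% of replicates while pure-decoy false positives stay
below α. Motifs mixing focal and background letters are excluded from the
decoy rate because in-place insertion genuinely perturbs them.

## Numerical and degenerate-input choices

* Empty inputs: filtering returns a zeroed ledger; counting returns an
  empty sparse matrix; profiles with zero occurrences are all-zero with
  n = 0 — none of these error.
* A motif spanning more than a sequence's length yields zero occurrences.
* Row order of count matrices is deterministic (size, shape, then motif
  string); frequency tables sort by descending fraction with ties broken by
  the canonical motif string; every output is byte-reproducible, which the
  pipeline test checks by hashing the full report bundle twice.
* "p = 1 for identical groups" is asserted to 1e-10.
* Generation and violation-planting save and restore the caller's RNG
  state; all randomness derives from explicit seeds.

## Problem sizes

The shipped analysis scripts and tests run at desk scale: presets of
500–1200 sequences for frequency/positional work, 150–400 for comparison
demos, 200 replicate pairs for calibration, 10^4 randomized cases for the
matcher-vs-regex-oracle equivalence check. These sizes give stable
qualitative results (binomial CIs a few percentage points wide) while the
full suite completes in minutes on a single core.

## Known limitations

* The Mann–Whitney observable (counts) and the BH family boundaries are
  choices where the original analysis is underspecified; both are exposed
  as arguments rather than fixed.
* Reduced-alphabet group membership for a few residues is reconstructed,
  not authoritative (see above).
* The region classifier is a formalization of hand-drawn annotations; its
  cutoffs are conventions, not fitted quantities.
* Multi-group comparisons are handled pairwise, each corrected within its
  own family; no global multi-group scheme is implemented.
* No background-model enrichment (observed/expected) is computed — reported
  fractions are raw presence frequencies by design.

## A worked example

```{r example, eval = FALSE}
library(gappedmotifs)

gen <- generate_peptides(preset_spec("two-taxon-demo", n = 400, seed = 5))
groups <- group_by_taxon(gen$records, c("Streptophyta", "Chlorophyta"))
mat <- count_matrix(gen$records, k_range = 2, mode = "count")
cmp <- mann_whitney_bh(mat, groups)
taxon_specific_motifs(cmp, min_fraction = 0.1)
```

The numbered scripts under `analysis/` run the same stages over all presets
and write their tables under `results/`.
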
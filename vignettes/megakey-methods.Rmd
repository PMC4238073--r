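---
title: "Coded descriptions and tolerant identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coded descriptions and tolerant identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megakey)
```

## The description model

A `megakey` description is a fixed-schema record: 29 morphological
characters of a male *Megaselia*, each with a typed value, optional
free-text remarks per character, general remarks, and opaque figure labels.
The schema trades expressiveness for objectivity: characters that depend on
absolute color judgments or that are rare *and* ambiguous are deliberately
absent. Rare but unambiguous features are written into remarks, which are
indexed for keyword retrieval, so a species with a unique feature (a
pigmented wing spot, say) is found instantly by searching for it rather
than by stepping through a key.

Character kinds and their value semantics:

| kind | storage | example |
|---|---|---|
| ratio / proportion / length (mm) | double, 2 decimals | SA ratio `1.00`, wing length `1.56` |
| coded categorical | state letter | labellum `c` ("dense") |
| count | state letter with open top | alular setae `d` ("4+") |
| costal section ratios | `c(C1, C2, 1)` | `1.25:1.00:1` |
| tarsomere interval | `c(lo, hi)` in 1..5 | `1-4` |
| setation order | token/operator chain | `T6~E~H<C` |

Measurement conventions built into the classifiers follow the printed
definitions exactly, with strict inequalities where the wording is strict:
a palpal seta exactly as long as the palp width is *short*; a hair at the
base of vein R exactly twice the vein width is *short*, not *long*; a
spinose labellum with exactly 30 setulae is *dense* (the sparse state is
"fewer than 30"). The costal index is computed as costa length divided by
wing length — the direction that keeps the index below 1 and matches the
published worked value (0.65); the classical verbal phrasing is sometimes
quoted inverted, and we document the convention rather than follow the
phrasing. Costal ratios are computed on raw section lengths and normalized
by C3, so scaling all three sections by any positive constant leaves the
stored value unchanged; rounding (half-up, two decimals) is applied once,
at encoding, never to already-rounded values.

Three codings deserve a note. The halter-color scale letters "lighter" (a)
and "darker" (c) in the printed template but leaves "same" unlettered; we
assign it "b" to keep codes contiguous. The labellum state list is printed
once as "not, sparse, or spinose" and defined once as "not spinose /
sparse / dense"; we use the canonical labels {not spinose, sparse, dense}
and accept "spinose" as an input alias for "dense" (flagged as a parse
warning), which is what lets the published example table parse unchanged.
A count of zero alular setae has no defined code; rather than invent one we
raise an `megakey_unsupported_state` error carrying the raw count. Two
further domain decisions: the SA ratio may exceed 1.00 (a ventral seta
longer than the dorsal is unusual but representable, and we see no basis
for a warning), and the unknown sentinel `?` is accepted for every
character and never auto-filled.

## File dialects

Descriptions travel in two dialects. The TSV dialect mirrors the printed
three-column table (label, value, remark) with the section headers
`Head / Thorax / Leg / Wing / Genitalia / General Remarks` and is meant for
humans; labels are matched case-insensitively after whitespace
normalization. The JSON dialect is keyed by stable character ids and is
meant for machines; ids are authoritative there. Both serializations are
deterministic and schema-ordered, and `parse(write(d))` reproduces `d` at
value level, including byte-for-byte remarks. The TSV dialect cannot carry
tabs or newlines inside text fields and refuses to write them; JSON has no
such restriction. Parsing is strict by default (an invalid cell aborts with
an aggregated error naming every offending character); lenient mode
downgrades invalid cells to unknowns and records warnings, which suits
transcriptions of legacy descriptions with gaps. Occurrence and
type-material metadata (Darwin Core) are out of scope: the record is the
character table plus remarks and figure labels.

The species matrix persists as a versioned JSON container of per-species
records, because cells are heterogeneous (letters, numbers, intervals,
expressions, unknowns); a flat CSV export is provided for spreadsheets and
is lossy (remarks are dropped). The keyword index is plain tokenization —
lowercase, punctuation stripped, whitespace split, no stemming — so a
search behaves predictably: every query token must occur among a species'
remark tokens.

## The identification engine

A query is a possibly partial description. For each species and character
the engine returns one of three verdicts: *unknown* (either side unknown;
skipped), *compatible*, or *incompatible*, under a tolerance configuration:

* numeric characters: compatible iff |q − r| ≤ t·r, where r is the value
  recorded in the matrix and t defaults to 0.10. Anchoring the window at
  the reference value means a species' published measurement defines its
  own acceptance interval, independent of the query.
* counts: absolute slack (default 0), with "4+" standing for any count ≥ 4.
* coded states: exact equality, with a match-level budget (default 0) of
  tolerated categorical disagreements.
* tarsomere intervals: exact interval equality.
* setation orders: pairwise strict-order consistency. Expressions are
  compared constraint-by-constraint, not as strings, because `T6~E~H<C`
  and `E~T6~H<C` encode the same ordering; `=` and `~` both mean equal
  rank, and only opposing strict orders on some token pair are a
  contradiction. This rule is deliberately tolerance-independent: an
  observer's `T6<E` cannot be distinguished reliably from a recorded
  `T6~E`, so equal rank never falsifies a candidate.

A species is a *candidate* when its categorical disagreements (coded
states, intervals, and order expressions) stay within the budget and every
measured character (numerics and counts) is within tolerance. Non-candidate
species are retained, ranked after all candidates — the intended workflow
narrows the fauna down and finishes the identification against the visual
aids, so deleting near-misses would be counterproductive. Ordering is
deterministic: candidacy, then mismatch count, unknown count, and taxon
name; ranks run 1..n without gaps.

The default tolerances (10% relative, 0 count slack, 0 budget) are
placeholders for expert calibration against real interspecific variation,
strict enough to be conservative and overridable per character.

`next_best_character()` drives an interactive-key loop: among unanswered
characters it maximizes the Shannon entropy of the surviving species'
state distribution. Numeric characters are binned in tolerance-width
windows (width = relative tolerance × the survivors' median value, so bins
mirror what the matcher can actually distinguish; with zero tolerance each
distinct value is its own bin); unknown cells are left out of the
distribution; ties break in schema order. When no unanswered character
separates the survivors the function signals `megakey_exhausted_key`
rather than returning an arbitrary pick.

## The synthetic fauna generator

`generate_species()` produces valid descriptions with controlled
statistical structure so that matrix and identification behavior can be
tested without collection data; taxon names are explicitly labelled
synthetic (`Megaselia sp-synth-001`, …). Coded states are sampled from
per-character weights (uniform by default); numeric values are drawn
uniformly from intervals bracketing the single published worked example
(wing length 0.8–3.0 mm, costal index 0.45–0.85, SA ratio 0.30–1.20, and
so on) rather than claiming genus-wide realism; foretarsal palisades run
from tarsomere 1 to a random distal end; setation orders are random
permutations with random operators. A rejection-sampling floor guarantees
any two species differ in at least `min_pairwise_separation` coded
characters (default 3), failing with a clear error after 10,000 attempts
if the floor is unattainable. `perturb_description()` simulates a second
specimen of the same species: independent multiplicative noise on each
numeric value (re-rounded at schema precision) and an exact number of coded
state flips.

What the generator does *not* emulate: trait correlations (real characters
covary phylogenetically and allometrically), measurement error structure
beyond uniform multiplicative noise, missing-data patterns of real slide
mounts, and near-cryptic species complexes (tests exercise a separation
floor of 1 as a harder case but do not assert perfect recovery there).
Passing the recovery suite therefore demonstrates internal consistency of
the tolerance engine — species separated by ≥3 coded characters, measured
with ±5% noise, are always recovered at rank 1 under the default 10%
windows — not identification performance on real faunas.

## Numerical and degenerate-input choices

Rounding is half-up at two decimals, implemented with a small epsilon
guard against binary representation of decimal midpoints; all schema
quantities are positive, so half-up and half-away-from-zero coincide.
Numeric tolerance checks add 1e-12 of slack so that equal rounded values
always compare compatible at zero tolerance. Empty matrices are legal,
searchable, and match nothing. Duplicate taxon names, truncated matrix
files, queries with no known characters, and tolerance overrides naming
unknown characters all fail with typed conditions
(`megakey_build_error`, `megakey_format_error`, `megakey_usage_error`)
rather than generic errors, so callers and the CLI can translate them into
exit codes.

## Problem sizes in the shipped suites

The test and acceptance suites run at desk scale by design: faunas of
5–200 synthetic species, 20 randomized oracle-equivalence cases, the
exhaustive 648-expression setation grammar sweep (4! token orders × 3³
operator choices), a 100-count boundary scan of the labellum classifier,
and a 50-species / 50-query recovery experiment at seed 42. These sizes
keep every property fully checkable by brute force while exercising the
same code paths a multi-thousand-species matrix would use.

## Known limitations

The schema is male-based, as is the template it implements; female
characters are not representable. Absolute colors are excluded by design.
The keyword index is free text: misspelled remarks are findable only by
the misspelling (the published workflow assumes curated remark wording).
Relative halter color occasionally disagrees with naive visual perception
on very dark or very light species — the coded value follows the relative
rule (halter knob vs scutum), not the absolute impression. Finally, the
table alone is not guaranteed diagnostic; it is the narrowing stage of a
workflow that ends with habitus, wing and genitalia images.
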
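---
title: "Mining collaborative motif tuples with mutation profiles"
author: "motifTuples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining collaborative motif tuples with mutation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifTuples)
```

## The model

`motifTuples` describes a sequence set by *ordered tuples of closed
frequent subsequences* and uses them as classification features. The
underlying assumptions are:

* functionally conserved sites appear as gap-less substrings shared by
  many sequences of a dataset, with variable length;
* several such sites can collaborate at *unbounded and variable*
  distances, so their co-occurrence and left-to-right order carry signal
  that fixed-width motif models and k-mer spectra cannot express;
* recurrent small deviations (one or two substitutions or indels) of a
  conserved site in the same dataset are themselves informative and
  should be scored by how often they recur, not discarded by exact
  matching.

The pipeline, exposed end-to-end as `featureGen()`, is:

1. `mineFrequentSubstrings()` — every substring with per-sequence support
   at or above a threshold, lengths bounded by `minLen`/`maxLen`,
   enumerated by prefix extension with per-node support-id sets (a prefix
   tree over all suffixes, depth-capped at `maxLen`). Support is counted
   per sequence (document frequency), because the closure rule below
   compares *sets of sequences*; total non-overlapping occurrence counts
   are carried along for the later combination stage.
2. `closureFilter()` — a candidate is dropped iff it is a proper
   substring of another candidate with an *identical* support set.
   Equality of support sets (not mere equal counts) is required: two
   substrings with the same frequency in different sequences are
   genuinely different features. Candidates longer than
   `keepLongestAbove` are never dropped, so long, specific sites survive
   even when a longer superstring happens to tie their support.
3. `buildOccurrenceTable()` / `expandDuplicates()` — a sparse sequence ×
   subsequence count table; a count of *n* for symbol α becomes presence
   of items α, 2α, …, nα, which reduces multiset mining to ordinary
   itemset mining and is lossless (the count is the largest *k* whose
   item is present).
4. `mineClosedCombinations()` — exactly the closed frequent itemsets
   (no item can be added without shrinking the supporting set), found by
   depth-first search with prefix-preserving closure extension. The DFS
   runs on an explicit stack rather than call-stack recursion so that
   thousands of symbols cannot exhaust R's recursion limit.
5. `deriveOrderedTuples()` — the dataset is re-scanned; each in-order,
   non-overlapping placement of a combination's members contributes one
   observed permutation, and permutations are pooled into tuples with
   placement frequencies.
6. `buildProfiles()` — each tuple is re-matched approximately
   (`matchTuple()`); exact placements increment the tuple's exact
   frequency, approximate placements increment the frequency of their
   canonical mutation record.
7. `encodeSequence()` — the descriptor component is 1 for an exact tuple
   match, `freq(record)/exactFrequency` for an approximate match whose
   record exists in the profile, 0 otherwise. `writeLibsvm()` emits the
   labeled sparse matrix; `toPSSM()` converts a profile into per-member
   position-specific scoring matrices.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `minSupport` / `supportRatio` | `minerConfig()` | none (exactly one required) | minimum number (or dataset fraction) of sequences containing a substring. Heterogeneous data (e.g. genome-wide binding peaks) needs very low ratios; small curated sets work with 0.3–0.5. |
| `minLen`, `maxLen` | `minerConfig()` | 1, 30 residues | substring length window. `minLen` should be near the expected motif length: it controls both specificity and mining cost, since all shorter frequent strings are enumerated on the way. |
| `keepLongestAbove` | `minerConfig()` | `Inf` (off) | length above which substrings bypass closure elimination. |
| `sub`, `ins`, `del` | `scoringScheme()` | −1 each | edit-event penalties (match is always 0). |
| `minScore` | `scoringScheme()` | −2 | failure threshold; with unit penalties this is "at most 2 edit events per tuple member". |
| `combinationSupport` | `featureGen()` | miner threshold | support for combination mining. |
| `tupleMinFrequency` | `featureGen()` | combination support | minimum pooled placement count for a permutation to become a tuple. |

The defaults for the scoring scheme are a deliberate, declared choice:
unit costs with a small cap are the simplest scheme that distinguishes
"slightly mutated site" from "absent site", and every value is
configurable. Substitution matrices and affine gaps (which protein work
would want) are out of scope.

## The approximate matcher

`approxMatch()` computes the maximum-score alignment of a whole pattern
against any substring of the text — operationally an edit-event automaton
over match/substitute/insert/delete transitions, implemented as a
dynamic programme with a free start and end in the text. Numerical and
tie-breaking choices, all of which exist to make results total and
reproducible:

* edits are anchored to 0-based *pattern* coordinates; an insertion
  records the observed base inserted in front of its pattern position;
* on equal score: fewer events win, then substitutions are preferred
  over deletions over insertions, then the leftmost span. The ordering is
  a package convention (any total order would do);
* a pattern-consuming position can carry at most one substitution or
  deletion by construction; several insertions may fall in front of the
  same position (forbidding that would break the equivalence with edit
  distance under unit penalties, which the test suite asserts against an
  independent dynamic-programming oracle);
* cells whose running score falls below `minScore` are pruned — scores
  only decrease along an alignment, so this is exact;
* `matchTuple()` is greedy left-to-right: each member takes its best
  match in the text remaining after the previous member, with no
  backtracking. With exact members this reduces to the leftmost-greedy
  placement rule used by the tuple miner, which the suite cross-checks.

Mutation records serialize as space-separated tokens
(`SUB member position patternBase observedBase`,
`DEL member position patternBase`, `INS member position observedBase`),
sorted by member, position and kind; serialization and parsing are exact
inverses.

## Occurrence counting and degenerate inputs

All exact occurrence counting (table cells, tuple placement, profile
scans) is leftmost-greedy and non-overlapping — deterministic and linear
time, and the same rule everywhere so the stages agree. Members of one
tuple placement may not overlap each other, since they model distinct
collaborating sites. Consequences worth knowing:

* when closure retains a substring of a tuple member as a separate
  symbol (their support sets differ), a closed combination may include
  both; such a combination has no non-overlapping placement and yields
  no tuples. This is a real limitation on datasets where a member's
  substring is independently frequent;
* a combination's support uses presence (at least one placement) while a
  tuple's frequency counts placements over the whole dataset, so a tuple
  frequency can exceed the dataset size;
* `mineFrequentSubstrings()` on a dataset that cannot meet the threshold
  returns an empty result (an error is raised only when the threshold
  resolves below one sequence); `featureGen()` turns an empty stage into
  a diagnostic suggesting a lower threshold;
* an empty profile (no exact placements, no records) cannot be converted
  to a PSSM; an approximate match against a profile with exact frequency
  0 scores 0, and a record more frequent than the exact count may
  produce components above 1 (allowed, flagged with a warning).

In the PSSM conversion, every consensus base starts at the exact
frequency; a SUB entry adds its frequency to the observed base at its
position; positions an entry does not touch accumulate the entry
frequency on the consensus base; DEL contributes nothing at its
position. INS and DEL are positionally ignored beyond that because a
fixed-width matrix cannot represent indels — a declared convention, not
a property of the data.

## The synthetic generator

`generateSyntheticDataset()` emulates the benchmark situation the
package is tested against: a fraction of sequences carries one exact
planted placement of a tuple (members separated by uniform random gaps,
flanked by uniform random background), further fractions carry variant
placements obtained by applying a fixed mutation record, and the rest is
pure background. Two guarantees make the returned manifest an exact
oracle:

* each generated sequence is rejection-sampled until scanning it with
  `matchTuple()` yields exactly the intended placement and record
  (backgrounds must yield none), and until no substring of a planted or
  variant member of length ≥ `guardLen` (default 7) occurs outside a
  planted span — otherwise chance junctions between background and a
  member would inflate substring supports and perturb closure;
* a variant record that the matcher would not itself report as the
  canonical best alignment (e.g. an indel placed ambiguously inside a
  homopolymer) is refused up front.

What the generator does *not* emulate: non-uniform base composition,
correlated background (repeats, low-complexity tracts), more than one
distinct planted tuple per call (concatenate sets via
`bindSequenceSets()` for mixtures), partial placements, and datasets
where motif substrings are independently frequent. Passing tests on
generated data therefore demonstrate algorithmic correctness under
controlled conditions, not robustness to every property of real
sequence collections.

## Problem sizes used by the test suite

The suite validates against independent oracles at sizes where the
oracles are exact and fast: 200 random datasets (≤ 12 sequences × ≤ 26
residues) against a full substring/support enumeration, 200 random
transaction tables (≤ 12 items) against a powerset closed-itemset
enumeration, 1,000 random pattern/text pairs (≤ 15 × ≤ 60) against a
dynamic-programming edit-distance oracle for score caps 1–3, and planted
12-mer tuples with gaps up to 500 residues at support ratio 0.3 in 60
sequences for end-to-end recovery. These sizes were chosen so that the
brute-force references remain unambiguous ground truth; the algorithms
themselves scale far beyond them.

## Known limitations

* Reverse strands are not searched; the tool operates on the given
  strand only.
* Infrequent positions *inside* a single frequent subsequence split it
  into two members; tolerating them is out of scope.
* Gap lengths between members are unbounded by design; there is no way
  to impose a maximum gap.
* Greedy tuple matching can miss a feasible approximate placement when
  a member's best-scoring match sits too far right; the descriptor then
  scores 0 for that sequence.
* Classifier training on the libsvm output is intentionally left to
  external tools.
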
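# motifTuples

Feature extraction for nucleic-acid (and protein) sequence classification
based on **collaborative frequent sequence patterns**: ordered tuples of
closed frequent subsequences with attached mutation profiles.

## The problem

Fixed-width motif models (PWMs) and k-mer spectra miss two things that
matter for classifying regulatory and non-coding RNA sequences: motifs of
*variable length*, and *long-range co-occurrence* — two conserved sites
that collaborate at an unbounded, variable distance. `motifTuples`
discovers such patterns directly from an unlabeled sequence set and turns
them into sparse numeric descriptors for downstream classifiers (SVMs,
random forests, ...). It is aimed at tasks like miRNA precursor
identification, piRNA identification, promoter recognition and protein
binding-site characterisation from ChIP-seq peaks.

## The method

Given a dataset *S₁ … Sₙ*:

1. **Closed frequent subsequences.** Every gap-less substring whose
   per-sequence support reaches a threshold (absolute count or dataset
   ratio) is enumerated over a depth-capped prefix tree of suffixes, each
   node carrying the set of sequence ids containing it. A substring that
   is part of a longer one occurring in *exactly the same sequences* is
   eliminated; only the super-string is retained (subsequences above a
   length bound can be exempted).
2. **Closed combinations.** A sparse sequence × subsequence occurrence
   table is built (leftmost-greedy, non-overlapping counts). Multisets of
   subsequences that co-occur frequently are mined as closed frequent
   itemsets; a symbol occurring *k* times is expanded into items
   α, 2α, …, kα so duplicates are handled by ordinary itemset mining. The
   search is a depth-first traversal with an explicit stack.
3. **Ordered tuples and mutation profiles.** Re-scanning the sequences
   turns each combination into ordered tuples FSSⱼ = ⟨m₁, …, mₖ⟩ with
   exact placement frequencies. Each tuple is then re-matched
   *approximately* (edit-distance automaton: match = 0, substitution /
   insertion / deletion < 0, failure below a score threshold), and every
   observed placement is summarised by a canonical mutation record such
   as `SUB 0 5 U C DEL 1 6 C` (kind, member index, 0-based pattern
   position, bases). The profile stores the exact frequency and the
   frequency of every record.
4. **Descriptors.** A sequence Sᵢ gets one component per tuple:

       c(Sᵢ, FSSⱼ) = 1                                    exact match
                   = freq(MTⱼₖ) / freq(FSSⱼ)              approximate match whose
                                                          record MTⱼₖ is in the profile
                   = 0                                    otherwise

   stacked into φ(Sᵢ) = [c(Sᵢ, FSS₁), …, c(Sᵢ, FSSₙ)], written as a
   labeled sparse (libsvm) file. Profiles can also be exported as
   position-specific scoring matrices (PSSMs).

## Worked example

```r
library(motifTuples)

# a benchmark set: 16 sequences with an exact planted placement of
# <GGAGAUG, UGGAGACU>, 7 with the variant "SUB 0 5 U C DEL 1 6 C"
g <- generateSyntheticDataset(23, c("GGAGAUG", "UGGAGACU"),
                              exactFraction = 16/23,
                              variantSpecs = list(list(
                                record = "SUB 0 5 U C DEL 1 6 C",
                                fraction = 7/23)),
                              alphabet = "RNA", seed = 1)

res <- featureGen(g$sequences, tempfile(), alphabet = "RNA",
                  supportRatio = 0.5, minLen = 7, maxLen = 8)
#> read 23 sequence(s)
#> mined 4 frequent substring(s) at support >= 12
#> 2 closed subsequence(s) after closure filtering
#> 1 closed frequent combination(s) at support >= 12
#> 1 ordered tuple(s) at frequency >= 12
#> profiled 1 tuple(s); 1 mutation record entr(ies) in total

res$profiles
#> MutationProfiles: 1 tuple profile(s)
#>   <GGAGAUG, UGGAGACU> exact 16, 1 mutation record(s)

# a sequence the tuple matches exactly scores 1.0 ...
encodeSequence("GGAGGAGAUGGGGUCCUGGAGACUAAG", res$profiles)
#> [1] 1

# ... and one carrying the recorded variant scores 7/16
encodeSequence("GGAGGAGACGGGUCCUGGAGAUAAG", res$profiles)
#> [1] 0.4375

matchTuple(c("GGAGAUG", "UGGAGACU"), "GGAGGAGACGGGUCCUGGAGAUAAG")$record
#> [1] "SUB 0 5 U C DEL 1 6 C"
```

The component 1 marks an exact tuple placement; 0.4375 = 7/16 is the
frequency of the observed mutation record relative to the tuple's exact
frequency — a recognised, recurrent variant of the pattern.

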
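---
title: "Sonifying coding sequences and scoring their consonance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sonifying coding sequences and scoring their consonance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musicodon)
```

## The model

`musicodon` treats a coding sequence as a piece of music. Reading the CDS in
frame from its first base, every codon becomes one bar of 3/4: a fixed
melodic formula of one to four solfège degrees (D, R, M, F, S, L, T — the
seven diatonic degrees, realized at semitone offsets 0, 2, 4, 5, 7, 9, 11
above a tonic) played under a fixed rhythm. The formula consists of a *base*
of one or two notes, optionally followed by one or two more notes, and the
rhythm is completely determined by that shape:

| base | following | rhythm (beats) |
|------|-----------|----------------|
| 1 | 0 | 3 (dotted half) |
| 1 | 1 | 2 + 1, or 1.5 + 1.5 when the formula collides (below) |
| 1 | 2 | 2 + 0.5 + 0.5 |
| 2 | 0 | 2 + 1 |
| 2 | 1 | 1.5 + 0.5 + 1 |
| 2 | 2 | 1.5 + 0.5 + 0.5 + 0.5 |

When the same melodic formula serves both a one-note-base codon and a
two-note-base codon (e.g. S followed by L, versus the two-note base S–L),
the one-note-base codon takes the dotted-quarter-plus-dotted-quarter scheme
instead of half-plus-quarter. This *collision rule* is what keeps the map
from codons to bars injective: every codon has a unique (pitches, durations)
bar, so a score can be detokenized back to its exact sequence
(`detokenize()` inverts `sonify()`).

Ten codon assignments are fixed by the source algorithm; the shipped table
extends them to all 64 codons by a deterministic convention (documented in
`?default_mapping`): the first base selects the base size (U gives one note,
A/C/G two), the dinucleotide prefix selects the base formula, and the third
base selects the appendage (A none, G appends R, U appends L, C appends MR),
falling back to M in the single case where the convention would duplicate an
attested bar. The extension is marked `provenance = "extended"` row by row
and can be replaced wholesale through `load_mapping()`; only the ten
attested rows are immutable. Whether the original 1995 table made the map
pairwise-distinct or merely well-defined is not decidable from its published
description; the shipped table enforces injectivity, and `load_mapping()`
only warns (rather than errors) when a user table leaves two codons with the
same bar, since such a table is still a valid sonification — it just cannot
be detokenized.

## Consonance analysis of ensembles

Two sonified voices are compared on an eighth-note grid: each bar
contributes six half-beat slots (the eighth note is the finest duration in
the rhythm table), and a note of *d* beats sounds in 2*d* slots. At a given
bar offset, every overlapping slot pair is classified by the absolute
semitone difference mod 12: unison (0), perfect fourth (5), perfect fifth
(7), or other — the tritone (6) counts as other, since only unison, fourth
and fifth are treated as consonances. The statistics are fractions of
overlapping slots: `f_unison`, `f_p45`, and their sum `f_cons`.

Ensemble alignment is gapless: `best_offset()` scans all integer bar
offsets in a window and maximizes `f_cons`, breaking ties toward the
smaller absolute offset and then toward the negative one. This makes the
by-ear trial-and-error alignment of ensembles deterministic; nothing in the
procedure suggests gapped alignment, so none is attempted.

Related sequences show up in three ways:

* **unison runs** — maximal stretches of bars whose six slot pairs are all
  unisons (`unison_runs()`);
* **melodic imitation (canon)** — one voice restating the other's bars at a
  positive lag, detected as maximal runs of identical *bar tokens*
  (formula + rhythm) at each lag (`imitation_lags()`); since the codon→bar
  map is injective, a bar-token match is exactly a codon match;
* **repeat runs** — within one voice, the longest run of an identical bar
  (`max_repeat_run()`), a summary of local sequence repetitiveness.

Both a strict slot-level unison statistic and the bar-token statistic are
exposed, because "unison" between two voices can reasonably mean either
pitch-only agreement or pitch-plus-rhythm agreement; the two coincide on
identical codons and differ only on bars that share slot pitches with
different formulas.

`permutation_test()` replaces a subjective "does this ensemble sound
consonant?" judgment with an empirical p-value: the bar order of the second
voice is shuffled (the permutation unit is the bar, i.e. the codon, so
within-bar structure is preserved), `f_cons` is recomputed at the same
offset, and `p = (1 + #{null >= observed}) / (n_perm + 1)`. Under
exchangeability this p-value is valid by construction; discreteness of the
statistic makes it slightly conservative.

All intervals are measured in the fixed C-major realization with every
pitch in one octave, so no compound intervals arise and `f_cons` is
invariant under transposing both voices by the same shift.

## Companion analyses

**Two-hybrid confidence filtering.** PBS (Predicted Biological Score)
categories A–D are e-value bands partitioning (0, 1):
A < 1e-10 ≤ B < 1e-5 ≤ C < 1e-2.5 ≤ D < 1. The printed chain uses strict
inequalities and does not say where a boundary value falls; `classify_pbs()`
sends it to the weaker (higher-lettered) category, consistent with reading
"A < 1e-10" as A strictly below the threshold. E (promiscuous prey), F
(proven artifact) and N/A are annotation-assigned, never derived from an
e-value, and are excluded from candidate filters by default. The published
47-record candidate table ships as a TSV fixture with its NF-κB and
gene-match flags.

**SID identity and epitope coverage.** Selected interacting domains are
extracted by 1-based inclusive coordinates, aligned with an in-package
global Needleman–Wunsch aligner (affine gaps: a gap of length L costs
`gap_open + L * gap_extend`, defaults 10 and 0.5; BLOSUM62 loaded from
Biostrings at run time rather than copied into this package — a
user-supplied matrix TSV is accepted via `read_submat()`). Percent identity
is `100 × identical columns / mutually non-gap columns`; for sets, both the
mean and the minimum pairwise identity are reported, because published
"more than X% identity" summaries are ambiguous between the two. Where a
SID is known on one protein only, `project_region()` maps its coordinates
through a full-length alignment onto a homolog, with endpoints in gap
columns moved inward to the nearest aligned residue. Epitope coverage is
the fraction of SID residues under the union of epitope intervals
(merged with `IRanges::reduce`, clipped to the SID); BED-like input files
are converted from 0-based half-open on read. Traceback ties in the aligner
break deterministically (substitution, then gap in the second sequence,
then gap in the first), so alignments are reproducible; tests check the
score against both a brute-force path-enumeration oracle and
`Biostrings::pairwiseAlignment`. The shipped protein triplet under
`inst/extdata/` is synthetic (clearly labeled so) and exists only to
exercise this pipeline without network access.

**SEC calibration.** The partition coefficient is
`Kav = (Ve − Vo)/(Vc − Vo)` — the formula is sometimes printed without
parentheses, but this is the standard kit definition (0 at the void volume,
1 at the geometric column volume; defaults Vo = 36 mL, Vc = 120 mL for a
HiPrep 16/60 Sephacryl S-100 column). The calibration model
`MW = a·e^(−b·Kav)` is fitted by ordinary least squares of ln MW (in Da) on
Kav, matching the printed exponential form; `r_squared` is reported in log
space. Standards are accepted in kDa and converted. `infer_oligomer()`
compares an observed weight with a monomer weight and names the nearest
integer multiple (monomer/dimer/trimer/n-mer) when the observed value falls
within a relative tolerance (default 15%) of that multiple, else
`ambiguous`.

## Synthetic data

The generators in this package produce the statistical structure the
analyses assume, not biological realism: uniform random codons (no codon
usage bias), paralog pairs made by substituting whole codons so the realized
codon identity hits the target within rounding (no dN/dS or transition
bias), canons made by prepending random filler, multinomial interaction
tables, and calibration standards lying exactly (or lognormally scattered)
on an exponential curve with Kav spread evenly over (0.1, 0.9). Passing
tests on these fixtures therefore show that the algorithms are correct under
their stated model, not that real genomes behave like uniform codon soup;
in particular, real coding sequences have long-range composition structure
that can inflate consonance between unrelated genes, which is exactly what
the permutation test is there to guard against. One user-facing seed drives
every generator; `derive_seed()` hashes a purpose string into an independent
31-bit substream so that, e.g., the paralog substitution positions do not
reuse the base-sequence stream.

## Numerical choices and problem sizes

* Bar durations are validated to sum to 3 beats within 1e-9; all grid
  arithmetic is integer.
* The permutation p-value uses the add-one estimator, so it can never be 0
  and is valid for any `n_perm >= 19`.
* Consonance tie comparisons use a 1e-12 slack so float noise cannot flip a
  tie-break.
* Test-suite problem sizes were chosen to keep the full suite under a
  minute on one core while leaving Monte Carlo margins wide: 1000 random
  CDS for the round-trip property, 200 repeats for permutation type-I
  calibration (99 permutations each, 60-bar voices), 50 pairs per point on
  a five-point identity grid for the monotonicity check, and brute-force
  alignment oracles up to length 8.

## Known limitations

* The published full 64-codon table is not available; results that depend
  on non-attested codons depend on the shipped extension convention.
  Bar-number-level reproduction of published ensembles (which also used a
  manual alignment) is out of reach for that reason, and is not attempted.
* MusicXML/MIDI output is content-equivalent, not byte-equivalent, to any
  particular engraving program's files; tempo (90 bpm) and tonic (C4) are
  presentation-only defaults, stated nowhere in the source method.
* The MIDI reader parses only the subset the writer emits (type 0/1, no
  running status).
* The aligner is a pairwise global aligner; multi-sequence summaries are
  built from all pairs rather than a true multiple alignment.
* `infer_oligomer()` assumes globular SEC behavior; anomalously eluting
  proteins will produce honest `ambiguous` calls rather than corrections.
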
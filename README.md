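# musicodon

Codon-level DNA sonification and music-theoretic sequence comparison, with
the companion analyses of a protein-interactome study.

## What this is for

Akirin/Subolesin (AKR/SUB) are deeply conserved nuclear regulators and
candidate anti-ectoparasite vaccine antigens that act almost entirely
through protein–protein interactions. One way to look at their coding
sequences — and at the sequences of their interaction partners — is to
*listen* to them: map every codon to a fixed bar of music and compare the
resulting voices polyphonically. Related sequences produce unisons, canons
and perfect fourth/fifth consonances; unrelated ones do not. `musicodon`
implements that sonification and makes the musical comparison quantitative,
alongside the ordinary computational steps of such a study:

* **Sonification** (`sonify`, `detokenize`): one codon per 3/4 bar; each
  codon has a fixed melodic formula of solfège degrees (D R M F S L T at
  semitones 0 2 4 5 7 9 11 above the tonic) and a rhythm fully determined
  by the formula's shape. The default 64-codon table is injective, so
  scores detokenize back to their exact sequence.
* **Ensemble analysis** (`consonance_profile`, `best_offset`,
  `permutation_test`, `unison_runs`, `imitation_lags`,
  `conservation_summary`): slot-level interval classification on an
  eighth-note grid, exhaustive gapless offset search, an empirical
  permutation p-value for "this ensemble is more consonant than chance",
  and detectors for unison runs and canons (melodic imitation = sequence
  homology).
* **Score I/O** (`write_musicxml`, `write_midi`, `write_tokens`):
  MusicXML 3.1, Standard MIDI File type 1, and a lossless token TSV.
* **Two-hybrid confidence filtering** (`classify_pbs`,
  `parse_interactions`, `filter_by_category`): PBS e-value categories
  A < 1e-10 ≤ B < 1e-5 ≤ C < 1e-2.5 ≤ D < 1, with the published 47-record
  AKR2 interaction table shipped as a fixture.
* **SID analysis** (`align_pair`, `percent_identity`, `project_region`,
  `epitope_coverage`): global affine-gap alignment of selected interacting
  domains, identity summaries, and protective-epitope coverage of a SID.
* **SEC calibration** (`kav`, `fit_calibration`, `predict_mw`,
  `infer_oligomer`): partition coefficient Kav = (Ve−Vo)/(Vc−Vo),
  exponential calibration MW = a·e^(−b·Kav) fitted in log space, and
  monomer/dimer/trimer calls.
* **Synthetic fixtures** (`random_cds`, `paralog_pair`, `canon_pair`,
  `random_interaction_table`, `synthetic_sec_standards`): seeded generators
  for every input, so all tests run offline.

## Worked example

```r
library(musicodon)

sonify("TGCGGATCTGCG")$bars
#>   bar_index codon formula durations
#> 1         0   UGC       T         3
#> 2         1   GGA      SL       2,1
#> 3         2   UCU      SL   1.5,1.5
#> 4         3   GCG     DRR 1.5,0.5,1
```

UGC is a single dotted-half-note T; GGA is the two-note base S–L as
half + quarter; UCU shares the S–L formula with a one-note base, so the
collision rule gives it two dotted quarters — every codon stays a distinct
bar. Now compare two voices, here a simulated paralog pair at 80% codon
identity:

```r
pp <- paralog_pair(200, target_identity = 0.8, seed = 11)
vA <- sonify(pp$a, label = "geneA"); vB <- sonify(pp$b, label = "geneB")
bo <- best_offset(vA, vB, max_offset = 10)
bo$profile
#> consonance_profile: offset 0 bars, overlap 200 bars; f_unison = 0.853, f_p45 = 0.049, f_cons = 0.903
permutation_test(vA, vB, bo$offset, n_perm = 999, seed = 11)
#> permutation_result: observed f_cons = 0.903, p = 0.001 (999 permutations)
head(unison_runs(bo$profile, min_len = 5), 3)
#>   start_bar end_bar length_bars
#> 1         0      12          13
#> 2        14      18           5
#> 3        20      29          10
```

85% of eighth-note slots are unisons and 90% are consonant, far beyond any
of 999 bar-shuffled null ensembles (p = 0.001): the voices are "related by
ear", with long unison runs marking the conserved stretches.

The companion analyses reproduce the study's published numbers:

```r
t1 <- parse_interactions(system.file("extdata", "akr2_y2h_table1.tsv",
                                     package = "musicodon"))
nrow(t1)                                    # 47 A-D candidate interactors
filter_by_category(t1, c("A", "B"))$name    # the 8 high-confidence ones
#> "AKR1" "ACTR10" "RNF10" "SF3A1" "THRAP5" "AKR2" "ESRRG" "PITPNA"

fit_calibration(synthetic_sec_standards(a = 166086, b = 3.377, n = 5))
#> calibration_curve: MW = 166086 * exp(-3.377 * Kav) Da (r^2 = 1.0000, log-space)
infer_oligomer(60.9, 30)
#> oligomer_call: observed 60.9 vs monomer 30 -> dimer (x2, tol 15%)
```

A command-line interface over the same functions lives at
`inst/cli/musicodon.R` (subcommands `sonify`, `ensemble`, `conserve`,
`y2h`, `sid`, `sec`, `simulate`).

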
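---
title: "Rule-based annotation of herbal multicomponent MS2 and the knockout acquisition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based annotation of herbal multicomponent MS2 and the knockout acquisition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladderms)
library(dplyr)
```

## The problem

Multi-herb preparations contain hundreds of metabolites spanning orders of
magnitude in content: saponins (ginsenosides, astragalosides), phenolic
acids, diterpenoid quinones, isoflavones, iridoid and phenylethanoid
glycosides. Untargeted LC-MS/MS with data-dependent acquisition (DDA)
collects MS2 spectra for the most intense precursors; characterizing them
relies on rule-based reasoning rather than spectral libraries of measured
intensities, because glycosides fragment predictably:

* the precursor sheds its sugar residues one at a time as neutral losses
  (Glc 162.0528, Rha 146.0579, GlurA 176.0321 Da, and 132.0423 Da for any
  pentose, which we label `Pen` because Xyl and Ara are isobaric);
* the chain terminates in a deprotonated aglycone ("sapogenin") ion whose
  m/z is diagnostic of the core: 475.38/391.29 for protopanaxatriol,
  459.38/375.29 for protopanaxadiol (the second value is the further loss
  of the C6H12 side chain), 455.35 for oleanolic acid, 489.36 for
  cycloastragenol, 457.37 for soyasapogenol;
* acylations announce themselves as CO2 / whole-malonyl (C3H2O3) or
  acetyl losses;
* non-saponin classes have their own loss grammar: danshensu (C9H10O5)
  units for salvianolic acids, methyl-radical/H2O/CO eliminations for
  tanshinones in positive mode, CH4/CH3OH losses for isoflavones,
  feruloyl for phenylethanoid glycosides.

`ladderms` implements this reasoning as a deterministic pipeline, plus a
DDA simulator that stands in for the instrument so every stage is
testable against a known ground truth at desk scale.

## Mass arithmetic and registries

All masses are most-abundant-isotope monoisotopic sums (C = 12 exactly).
Charged-species arithmetic includes the electron mass, so the
deprotonation delta is -1.007276 Da; this is what makes the computed
values agree with published 2-dp ion tables. The adduct registry contains
exactly the negative adducts -H, +HCOO, +CH3COO, +Cl, +e and positive
+H, +Na, -e, all singly charged; multiply charged species and isotope
patterns are out of scope. The neutral-loss vocabulary and adduct table
ship as JSON under `inst/extdata/` and print from `neutral_losses()` /
`adducts()`.

One numeric choice deserves a note: monomalonyl loss is sometimes quoted
as "44.01 Da" alongside 86.00 Da. The theoretical CO2 mass is 43.9898 Da
and 86.0004 Da is C3H2O3; the registry uses the theoretical values and
treats the 44.01 quotation as a transcription artifact. Matching of
diagnostic ions uses an absolute +/-0.02 Da window (they are tabulated at
2 dp, mixing observed and theoretical values); everything else matches at
10 ppm, the conventional accurate-mass tolerance of the acquisition
software this pipeline emulates.

## The compound library

A library is a validated tibble: id, name, Hill formula, a closed class
vocabulary (ginsenoside, astragaloside, phenolic_acid, tanshinone,
flavonoid, iridoid, phenylpropanoid, other), source herb, optional sugar
composition (`"Glc:2;Pen:1"`), optional curated loss sequence, acyl
counts, expected retention time and a reference-standard flag.
Validation recomputes the neutral mass from the formula and, when both a
sugar composition and an aglycone are given, checks that aglycone +
dehydrated residues + acyl groups reconcile with the formula to 1e-3 Da.
Isomers are distinct records; queries return all of them and never pick
an arbitrary winner.

The packaged `four_herb_library()` holds 43 records restricted to compounds
whose identity is published for the four-herb formula the package is
demonstrated on; retention times are published values where available
and synthetic placements (inside the corresponding knockout windows)
for compounds known only from the waste-switching schedule. Larger
libraries for scale tests are drawn by the generator, not shipped.

```{r}
four_herb_library() |> count(class)
```

## The annotation pipeline

`annotate_spectrum()` runs, in order: adduct hypothesis generation
(every polarity-compatible adduct against the library at 10 ppm),
depth-first loss-chain search from the (de)protonated-molecule node
(when the precursor is a formate/acetate adduct the adduct loss is the
implied first step), diagnostic sapogenin classing, malonyl detection,
glycan-composition inference, and candidate scoring.

Determinism is a design goal, so every choice has a specified
tie-break: chains are enumerated in lexicographic loss-name order and
each step lands on the nearest matching peak; when several chains could
carry the glycan reading, the one terminating on a sapogenin diagnostic
wins, then longer chains, then more sugar-typed losses, then
lexicographic order; candidates are ranked by score, then absolute ppm,
then id. The chain search is bounded at depth 8 by default; hitting the
bound flags the chain `truncated` rather than erroring. A fragment must
exceed 5 counts to support a chain step, mirroring the MS2 intensity
threshold of the emulated workflow.

The score of a candidate is the matched fraction of its rule-derived
theoretical fragment set (sugar ladder + acyl losses + diagnostics +
class rules), floored at 0.1 for precursor-only evidence. The floor and
the `library_matched` threshold of 0.3 are package choices - the
emulated vendor software publishes only qualitative criteria - and sit
deliberately far apart: a precursor-only match can never clear the
threshold. Confidence is graded `identified_reference` (a
reference-standard record matching mass, retention time within 0.2 min,
and at least one fragment) > `library_matched` (top score >= 0.3) >
`class_characterized` (diagnostics fired but no library candidate
qualified) > `unknown`.

```{r}
lib <- four_herb_library()
sp <- theoretical_spectrum(lib[lib$id == "noto_r1", ], "negative")
sp$rt_min <- 5.74
annotate_spectra(sp, lib) |>
  select(top_id, score, confidence, sapogenin, sugar_composition)
```

## What the simulator emulates - and what it does not

`simulate_dda()` models: Gaussian elution peaks (width is configurable;
no published peak-shape model exists for the emulated runs, so the
default sigma is 0.05 min, a typical sub-2-um UHPLC peak), log-uniform
abundances over a configurable dynamic range (default 3 decades),
top-N precursor selection above a 1000-count threshold, MS2 acquisition
time that shortens for intense precursors (the 2000-count TIC stop
criterion against the 1.5 s budget), dynamic exclusion (default 6 s;
the emulated method does not document one, so it can be set to 0), and
knockout windows that zero all signal while active - the physical
waste-switching valve. On-column load enters as a multiplicative
abundance factor, so the published three-injection protocol (1 mg/mL x
3 uL; 10 mg/mL x 3 uL; 10 mg/mL x 5 uL - a 16.7-fold load increase) is
expressible in configuration.

It does not model ion-mobility drift, detector saturation, isotope
envelopes, in-source fragmentation, chromatographic tailing, or
intensity variability; MS2 spectra are the rule-derived fragment sets
with a fixed intensity profile plus optional uniform noise peaks.
Passing recovery tests on these spectra therefore demonstrates the
logical correctness and determinism of the annotation rules, not
robustness to real spectral noise, co-isolation or calibration drift.

## The knockout demonstration

The packaged demonstration mirrors the motivating acquisition protocol.
`demo_knockout_mixture()` is a constructed (non-random) ground truth:
one dominant saponin at 11.2 min (4e5 counts, sigma 0.05 min) and the
36 negative-mode-annotatable library compounds as minors (300-900
counts, sigma 0.12 min) sharing its elution window. At reference load
the minors sit below the trigger threshold and only the dominant is
characterized. The knockout injection raises the load 16.7-fold and
diverts the dominant's apex (11.05-11.35 min) to waste: the minors now
trigger on the window flanks and annotate correctly. This is the same
trade the physical protocol makes - the dominant peak, already
characterized at low load, is sacrificed to expose what it shadowed.
Note that with a physical eluate-diversion model a window by itself can
only remove signal; the exposure gain comes from the combination of
higher load and waste-switching, which is why the comparison runs the
whole protocol rather than toggling the window alone. A separate
containment property (windows covering only the dominant apex never
lose minors, on time-separated mixtures) is part of the test suite.

The demonstration uses a 60 s dynamic exclusion so trigger slots rotate
through fresh components rather than re-sampling the most abundant
minors; with the 6 s default the conclusion is unchanged but fewer
distinct minors are collected per scan budget.

```{r, eval = FALSE}
cmp <- run_knockout_comparison(seed = 1)
cmp
#> <knockout_comparison> baseline 1 vs knockout 31 components correctly
#> annotated (+30, load x16.7)
```

## Numerical and scale choices

* Tolerance windows are closed intervals with a 1e-9 ppm slack so
  exact-edge queries are inside despite floating-point rounding.
* Theoretical fragment sets deduplicate nodes that coincide to 1e-3 m/z
  (the full sugar-ladder terminus and the deprotonated sapogenin are the
  same ion by construction).
* The cycloastragenol rearrangement ion at m/z 383.29 (furan-ring
  cleavage) has no assignable elemental loss and is stored at its
  reported 2-dp value; every other diagnostic is formula-derived.
* Test and acceptance problem sizes are desk-scale by design: the
  43-record fixture library, 500-case oracle comparisons for the chain
  search, and single-run simulations of a ~12-minute window. These sizes
  keep the full suite under a minute while exercising every rule path.

## Known limitations

Positive-mode saponin logic is deliberately absent (in-source
fragmentation makes it uninformative on the emulated instrument), so
saponins are annotated from negative-mode data only. Retention-time and
CCS prediction are out of scope; CCS is pass-through metadata.
Structure-level identification of isomer families (pervasive among
ginsenosides) is not attempted: tied isomeric candidates are all
reported, as a practitioner would expect.
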
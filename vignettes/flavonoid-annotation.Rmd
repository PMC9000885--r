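---
title: "Multi-tiered MS/MS annotation of flavonoids: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tiered MS/MS annotation of flavonoids: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavotier)
```

## The problem

Untargeted LC–MS/MS of plant extracts produces thousands of fragment spectra
whose structural assignment carries very different degrees of certainty. The
community convention (the Schymanski scale) grades annotations from level 1
(confirmed against a purchased standard) through 2a (spectral-library match),
2b (diagnostic evidence from candidate structures), 3 (a tentative candidate
set, e.g. positional isomers), down to 4 (molecular formula only) and 5
(exact mass only). `flavotier` implements that tiering for positive-mode
flavonoid spectra, together with the subclass fragmentation rules used to
*validate* annotations: flavonoids fragment predictably by retro-Diels-Alder
(RDA) ring cleavage, and the identity and relative intensity of the resulting
A-ring / B-ring ions and small neutral losses (CO, H2O, CH3·) are diagnostic
of the subclass.

## Mass arithmetic

All m/z values derive from a four-element monoisotopic mass table (C, H, O,
Na) and an explicit electron mass. Singly charged cations are computed as the
atom inventory minus one electron, so a protonation adds 1.007276 Da, not the
hydrogen atom mass. This correction is what makes fragment values such as
241.0495 and 213.0546 ([M−CO+H]+ and [M−2CO+H]+ of the coumestan-type
neoflavonoid) come out right at the fourth decimal.

Formula decomposition of an observed m/z enumerates C/H/O compositions
exhaustively within user bounds, keeps candidates within an absolute mDa
tolerance, and filters to chemically sane compositions: rings-plus-double-bond
equivalents (RDBE = C − H/2 + 1) in [0, 25] and H ≤ 2C + 2. Candidates are
ordered by absolute mass error with fewer oxygens breaking ties. The element
palette is limited to C/H/O (Na only as an adduct) because flavonoid
chemotypes contain nothing else; this is a deliberate scope restriction, not
a shortcut.

## The subclass model

Twelve subclasses are registered: flavone, flavonol, isoflavone, flavanone,
chalcone, flavanol, aurone, and neoflavonoid types I, II, III, IV and VIII.
Each skeleton record carries:

* a scaffold formula (e.g. C15H10O2 for flavone, C15H12O2 for flavanone);
* RDA cleavage templates, each naming the two bond positions broken (the
  field's `i,j` notation) and giving the neutral part formulas of the A-side
  and B-side products. The invariant `part_a + part_b == scaffold` is
  asserted every time the registry loads, which guards the hand-transcribed
  data;
* a diagnostic ion list (which cleavage products appear, with what hydrogen
  transfer and electron parity, plus neutral-loss series), tiered 100/60/20
  by the qualitative intensity language of the underlying descriptions
  ("base peak", "strong", "observed");
* a rule: which ions are mandatory, which ion must be the base peak, and any
  fragment-intensity share condition.

Substituents are restricted to hydroxyl (+O), methoxyl (+CH2O) and methyl
(+CH2) on ring regions A, B and C — this covers the reference chemotypes.
Ring-A substituents decorate the A-side cleavage product, ring-B the B-side;
ring-C substituents follow the part that retains the relevant atom, recorded
per cleavage.

Two data-modeling choices deserve a note. First, the "flavanol" anchors
(taxifolin, dihydromyricetin) are chemically dihydroflavonols, so that
subclass uses the 3-hydroxyflavanone scaffold C15H12O3 — with a flavan-3-ol
scaffold their formulas would be wrong by H2. Second, the compound slot named
tangeretin sits, as in the source numbering, inside the flavanone block; its
template is a representative pentamethoxy flavanone-slot template, and its
formula follows the template algebra. Part formulas of the rarer
neoflavonoid cleavages (II, VIII) are transcribed representatives: the
printed diagnostic ions carry no formulas, so only the conservation
invariant constrains them.

The flavanone/chalcone pair shares identical cleavage conventions by design:
these two subclasses are not distinguishable from an MS/MS spectrum alone
(the discrimination requires UV data, which is out of scope), so the
classifier reports them as one equivalence class.

## Rule verification and classification

`verify_annotation()` matches a template's expected ions against the
normalized spectrum at an absolute, inclusive mDa tolerance (default 10 mDa,
the fragment-tolerance convention of the emulated workflow) and passes only
if (i) the template formula is consistent with the precursor m/z, (ii) all
mandatory ions match, (iii) the designated base ion is the observed base
peak, and (iv) any share condition holds — for flavanones/chalcones the
1,3 A-ring ion must carry at least 40% of summed fragment intensity
(precursor excluded). The explained-intensity fraction (matched intensity
over total) is used for ranking only, never for pass/fail, so decoy peaks
can dilute a score but cannot flip a verdict.

`classify_spectrum()` enumerates, for each subclass, all substituent
placements consistent with the precursor formula (at most 3 oxygen-bearing
substituents per ring, which bounds the search and covers the fixture
chemotypes), verifies each, and ranks passing subclasses by explained
intensity. The substituent algebra makes the enumeration cheap: hydroxyls
add O, methoxyls and methyls each add exactly 2 H, so a formula excess
decomposes into at most a handful of (OH, OMe, Me) counts.

## Fragmentation trees

Level-3 evidence uses a simplified fragmentation-tree engine. Peaks are
annotated with subformulas of the precursor cation (carbon-containing, H ≤
2C + 2) minimizing absolute mass error within tolerance; unassignable peaks
are kept, labeled as such. Each non-root node then attaches to the heavier
node minimizing an edge cost: losses explicable as a composition of at most
two common losses (CO, H2O, CH2O, C2H2O, CH3·, CH4, CO2, C8H8) cost 0,
anything else costs 1, with ties broken by smaller loss mass. Methyl-radical
losses are limited to one per root-to-leaf path (the even-electron rule),
configurably. Because every candidate parent contains the child's formula
and the precursor contains everything, the procedure always yields a tree;
it is a readable neutral-loss summary rather than an exhaustively optimized
tree, and it is validated structurally (conservation on every edge and
path), since no reference tree scores exist to compare against.

## In-silico fragmentation (level 2b)

Candidate structures are ranked MetFrag-style: each skeleton has a
bonded-atom graph (explicit per-atom hydrogen counts, so fragment formulas
are exact inventories without valence bookkeeping); substituents are grafted
onto substitutable ring positions. Breaking one bond, or any pair of bonds
whose joint removal disconnects the graph (two acyclic bonds, or a pair
opening one ring), yields fragment components, each emitted with hydrogen
rearrangement variants at −1/0/+1 H. A candidate's score is the fraction of
query intensity explained by these fragments plus its diagnostic ions; ties
are broken by rule-verdict pass and then parsimony (fewer theoretical
fragments). Positional isomers with identical scores are flagged
indistinguishable rather than resolved arbitrarily.

## The tiering pipeline

Per query, evidence is gathered strictly in level order with the defaults:

| parameter | default | meaning |
|---|---|---|
| RT tolerance | 0.05 min | level-1 retention-time gate |
| MS1 tolerance | 5 mDa | level-1 precursor gate |
| MS2 tolerance | 10 mDa | fragment matching and 2a precursor pre-filter |
| 2a score cutoff | 80% (inclusive) | library-hit threshold |
| quasi-reference cutoff | 90% (strict) | promotion threshold |
| min. matched fragments | 3 | level-1 "matching fragment ions" gate |

The similarity score is either the normalized dot product over the full peak
vectors (unmatched peaks contribute zero to the numerator) or spectral
entropy similarity, `1 − (2·S_merged − S_a − S_b)/ln 4`, with intensities
normalized to sum 1 and the merged spectrum the peak-aligned average. Raw
intensities are used in both — the commercial engines' internal weightings
are unpublished, and raw weighting is the simplest defensible choice. The
minimum fragment count of 3 for level 1 is likewise a configurable choice
where the source states only "matching fragment ions". At level 3, up to ten
decomposed formula candidates are tried and the first yielding a subclass
ranking is kept, mirroring how de novo engines consider a formula candidate
list rather than the single best mass error.

Level-2a results scoring strictly above 90% are re-emitted as
quasi-reference library records (provenance `quasi-reference-2a`); the
strict inequality versus the inclusive 2a cutoff mirrors the distinction
between "cutoff, 80" and "higher than 90%" in the underlying protocol.

## What the synthetic generator emulates — and what it does not

`build_quasi_library()` constructs the 39-compound fixture set (18 named
standards plus representative quasi-reference templates) with the exact
12-subclass composition, noise-free theoretical spectra, and retention times
on a 0.6-min grid — spaced so the 0.05-min level-1 window is genuinely
discriminating. `simulate_spectrum()` adds Gaussian m/z jitter (default σ =
3 mDa on fragments; σ/4 on the precursor, because the emulated acquisition
records the survey scan at four times the fragment-scan resolution),
multiplicative intensity noise (default 10%), and uniform-random decoy peaks
(default 5 peaks at 5% relative intensity). All randomness flows from a
single mandatory seed.

`simulate_dataset()` assigns designed levels by partitioning templates into
evidence groups — level-1 templates into the standards list (and library),
2a into the library only, 2b into the candidate list only, 3 withheld
everywhere. The partition keeps same-precursor-formula templates in one
group: a designed-2b query with a spectrum-identical or same-formula twin
sitting in the library would have an ill-defined designed level, and the
benchmark is meant to measure tier assignment, not isomer ambiguity (which
the 2b ranking exercises separately). Benchmark sizes used by the test
suite: 200 classification spectra and a 200-query mixed-level pipeline run
(10/40/30/20% across levels 1/2a/2b/3), chosen to estimate recovery rates
with a few-percent margin while keeping the default suite quick.

The generator does **not** emulate: collision-energy-dependent intensities
(the dominant source of real library-search score variation),
instrument-to-instrument differences, chromatographic peak shapes or
co-elution, isotope patterns, glycosylated or acylated flavonoids, or
negative-mode chemistry. Passing the synthetic benchmark therefore
demonstrates internal consistency of the tiering logic and rule engine under
calibrated noise — not performance on real instrument data.

## Numerical choices and degenerate inputs

* All tolerance comparisons are inclusive, with a 1 ns-scale epsilon so that
  values exactly at the boundary (e.g. a 10.000 mDa difference) match.
* Peak matching is greedy on descending intensity product (deterministic,
  m/z tie-break), not optimal bipartite matching — the standard choice in
  spectral search.
* The all-zero formula is representable and is the identity of formula
  addition; a formula is a subformula of itself with zero difference, which
  keeps fragmentation-tree roots and zero losses regular.
* Empty decomposition results, empty subclass rankings and queries without
  retention time are regular return values (with reasons or warnings), not
  errors; a malformed query inside a batch is reported per-query and never
  aborts the run.
* Spectra that coincide in m/z after decoration are merged keeping the
  highest intensity tier.

## Known limitations

Positional isomers within a subclass are not resolved (the rule engine
flags them); biflavones and fatty-acid flavonoids are out of scope; the
neoflavonoid II/VIII cleavage parts are representative transcriptions; and
the simulator's intensity model is a three-tier convention, so
explained-intensity fractions on real spectra will differ from the synthetic
values even when the ion content matches.
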
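---
title: "Identifying lipoteichoic acid primer lipids by in-silico fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying lipoteichoic acid primer lipids by in-silico fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltafrag)
```

## The problem

Lipoteichoic acid (LTA) is the major lipid-anchored anionic polymer of
Gram-positive cell envelopes. In *Bacillus subtilis* its glycolipid anchor is
a diacylglycerol (DAG) carrying a diglucose head group; the nascent polymer
("LTA primer", LTAP) adds a single phosphoglycerol unit to the non-reducing
glucose, and the DltABCD machinery esterifies glycerol hydroxyls with
D-alanine, partially neutralising the surface charge. Direct-infusion
electrospray MS of cold-extracted polar lipids can reveal the anchor, the
primer and its mono- and di-alanylated forms, but only if one can (i)
predict the exact masses of these species and of their collision-induced
fragments, (ii) match noisy observed peak lists against those predictions,
and (iii) emulate the three diagnostic precursor-ion scans that pick the
relevant species out of a crowded membrane extract. `ltafrag` implements
that pipeline, together with a seeded synthetic-spectrum generator so every
stage is testable without instrument data.

## Mass arithmetic

All masses derive from a closed element table (C, H, N, O, P, Na) with
monoisotopic masses of the most abundant isotopes (C = 12 exactly,
H = 1.007825, N = 14.003074, O = 15.994915, P = 30.973762, Na = 22.989770)
and integer nominal masses. Molecules are condensation products of free
residues — glycerol C3H8O3, glucose C6H12O6, phosphate H3PO4, alanine
C3H7NO2 and fatty acids C~n~H~2n-2d~O2 — with one water removed per ester,
glycosidic or phosphodiester bond.

Ion conventions: sodiated cations add the sodium *atom* mass with no
electron-mass correction; deprotonated anions subtract the proton mass
(1.007276); doubly deprotonated dianions subtract two protons and halve.
The reference fragment tables this package reproduces mix two conventions
internally: their large anions match proton subtraction while their small
anions (88.0399, 241.2169, 152.9953) match hydrogen-*atom* subtraction,
about 0.0005 amu apart. One convention (proton subtraction) is used
throughout and the comparison tolerance absorbs the difference. Comparisons
are made in absolute amu (default 0.002 for calculated values, matching the
agreement the source data claim for themselves) rather than ppm, because
the reference agreement is itself stated in amu.

## The fragmentation model

Each lipid class is a tree-shaped residue graph. Every condensation linkage
carries two flanking scissile bonds, one on each side of the bridging
oxygen, labelled as in the reference structure drawings:

| linkage                     | O stays with...     | labels |
|-----------------------------|---------------------|--------|
| acyl ester (chain *i*)      | glycerol / acyl     | a~i~ / b~i~ |
| glycerol-glucose            | glucose / glycerol  | c / d  |
| glucose-glucose (glycosidic)| inner glucose       | f      |
| glucose-phosphate           | phosphate / glucose | g / h  |
| phosphate-head glycerol     | head glycerol / phosphate | i / j |
| head glycerol-alanine 1     | alanine / glycerol  | k / l  |
| head glycerol-alanine 2     | alanine / glycerol  | m / n  |

Cutting a bond sends the bridging oxygen (plus a transferred hydrogen) to
one side: that side keeps its water of hydrolysis, the other side leaves
dehydrated. Summing free-residue formulas, subtracting one water per intact
internal linkage and one more per "dry" cut reproduces the whole
`- H` / `- H3O` / `- H5O2` suffix family of the reference tables without
per-row rules. `enumerate_fragments()` cuts every subset of up to
`max_cuts` linkages (default 2, or 3 for alanylated classes, which show
triple-cut fragments), emits every charge-retaining side in every water
state, and deduplicates by (composition, adduct) so that cuts of two
identical acyl chains collapse, as the reference tables note. The second
flank of the glycosidic bond is never assigned in the reference tables and
is not enumerated; its cuts only duplicate compositions already reachable
through labelled bonds. Fragments below m/z 50 are suppressed (no observed
fragment lies below 79).

Three channels go beyond plain water bookkeeping:

* **Allylic double acid loss.** When both acyl esters are cut and both
  acids leave with their water, the glycerol retains two hydrogens and the
  allylic `CH2=CH-CH2-Glc-Glc + Na+` cation results (m/z 405.137); plain
  bookkeeping would be two hydrogens light.
* **Positive-mode adducts.** Cations containing a hexose are sodiated (the
  sodium rides on the sugar); hexose-free cations appear as dehydrated
  protonated ions, the `[MAG - OH]+` type, which agrees with the reference
  values to within the electron-mass scale.
* **Rearrangements.** Only the di-alanylated primer yields the deprotonated
  alanyl-alanine dipeptide (159.078) and the decarboxylated molecular anion
  (M - CO2 - H, 1115.661); both require a two-step rearrangement and are
  emitted by `special_rearrangements()` rather than by bond cutting.

Cardiolipin and lyso-cardiolipin are catalogued as molecular ions only
([M-H]^-^ and [M-2H]^2-^): their fragmentation is outside the scope of this
pipeline, which only needs their precursor clusters in full scans.

One reference value is treated as an erratum: the `(15:0) MAG-Glc-Glc-P -
H3O` fragment is printed as 701.3051, but its own `- H` companion (719.3257)
fixes the `- H3O` form at exactly one water lighter, 701.3151, and
recomputation from the composition C30H59O16P gives 701.3155. The package
reports the self-consistent value.

A second data point exceeds its stated accuracy: in the sodiated-anchor
table the observed 483.2907 peak lies 0.0027 amu from its recomputed
theoretical value (and 0.0029 from the printed one) although the data claim
0.002 agreement overall; the acceptance suite flags exactly this row.

## Annotation and precursor-scan emulation

`annotate_spectrum()` greedily assigns each observed peak the nearest
catalog ion within an absolute tolerance (0.005 amu suits Q-TOF-class data,
0.3 amu unit-resolution data), breaking ties by fewer cuts and then by
cleavage label; unmatched peaks are reported, never force-assigned. Global
bipartite matching is unnecessary at these peak densities — the reference
tables pair peaks and fragments 1:1.

Three diagnostic ions drive species discovery: sodiated dehydrated
diglucose (347.095, positive) for dihexose head groups, the cyclic
glycerophosphate anion (152.996) for free terminal phosphoglycerol, and
deprotonated alanine (88.040) for ester-linked alanine.
`precursor_scan()` turns a set of MS/MS spectra into a precursor-scan
trace; `nominate_species()` inverts a (precursor m/z, diagnostic) pair into
ranked candidate species by searching the diagnostic-compatible classes
over acyl sum compositions C 24-40, double bonds 0-4 — a grid wide enough
for the odd-chain (15:0/17:0-dominated) *B. subtilis* acyls. Within that
grid no two candidate precursors of one diagnostic lie within 0.01 amu, so
nomination is stable against instrument-scale m/z error.

## The synthetic-data generator

`simulate_msms()` draws one peak per catalog ion with Gaussian m/z jitter
(presets: 5e-4 amu "qtof", 0.2 amu "qtrap") and log-normal arbitrary-unit
intensities, plus uniform background peaks; everything is deterministic
given the seed. `simulate_full_scan()` places abundance-scaled molecular
ions of a mixture (cardiolipins mainly as dianions at half m/z);
`bsubtilis_mixture()` encodes the qualitative cluster structure of the
*B. subtilis* extract — dominant (30:0)/(32:0) PG at 693/721, cardiolipin
dianions at 650-680 and anions near 1300, dehydrated lyso-cardiolipin near
1100, alanyl-PG at 764/792, the LTA primer at 1017/1045 and the alanylated
primers at 1088/1116 and 1159/1187. Its relative abundances are
order-of-magnitude settings chosen once to reproduce the described
intensity ordering; they are not measurements.

`simulate_precursor_scan()` composes per-species MS/MS simulations and
keeps precursors whose spectrum shows the diagnostic ion. It defaults to
`max_cuts = 1`: a collision-energy-optimised precursor scan reads out the
dominant single-dissociation channel, so species whose phosphoglycerol is
embedded (cardiolipin) or alanine-capped (alanyl-PG, alanylated primers)
are dark in the 153 scan — releasing their glycerophosphate would need two
or three simultaneous cleavages. When deeper catalogs are simulated, those
species' 153 peak is damped to 5% instead, reflecting the weak embedded
emission seen experimentally. The generator emulates peak positions,
m/z error and crude intensity ranking only; it has no isotope envelopes,
chromatography, charge states beyond 2-, detector saturation or
collision-energy dependence, so passing round-trip tests demonstrates the
correctness of the arithmetic and matching logic, not instrument realism.

## Numerical and design choices

* The second alanine of the di-alanylated primer is attached to the head
  glycerol; the source data are explicitly not definitive on its position,
  and every candidate position is mass-invariant, so only the m/n bond
  labels depend on this convention.
* Unresolved sum compositions default to the dominant odd-chain split
  ((30:0) to 15:0/15:0, (32:0) to 17:0/15:0, larger chain first so that
  chain indices match the reference cleavage labels); sn-positions are not
  modelled (mass-invariant, never assigned at source).
* The hexose is fixed to glucose; galactose variants, polymerised LTA with
  more than one phosphoglycerol, wall teichoic acids, lysyl-PG and
  isotope-pattern prediction are out of scope.
* Ties and degenerate inputs: empty spectra annotate to empty reports;
  zero-length peak files produce empty spectra with a warning; annotation
  with an enlarged tolerance can only gain matches (greedy per-peak
  nearest assignment).
* D- versus L-alanine is indistinguishable by mass and is not modelled.

## Problem sizes in the test suite

The test suite reproduces all 52 transcribed reference fragment rows,
round-trips all eight lipid classes noiselessly, verifies catalog recovery
on 100 seeded noisy spectra (sigma = 0.001 amu, 50 background peaks) and
species nomination on 100 seeded runs cycling through the six
diagnostic-linked classes, and checks the bond-cutting enumerator against a
brute-force sub-multiset oracle on a four-residue toy graph. These sizes
keep the default suite under a minute on one CPU while leaving the
statistical thresholds (>= 95% recovery, >= 99% nomination accuracy)
binomially well-resolved.
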
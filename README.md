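# ltafrag

In-silico fragmentation and annotation of the lipoteichoic acid (LTA)
glycolipid anchor, the LTA primer and their alanylated derivatives in
*Bacillus subtilis* direct-infusion mass spectra.

Gram-positive bacteria anchor lipoteichoic acid — a polyanionic
phosphoglycerol polymer — to the membrane via a diacylglycerol-diglucose
(DAG-Glc-Glc) glycolipid, and partially neutralise it by D-alanylation of
glycerol hydroxyls. The biosynthetic intermediates of this pathway (the
anchor, the single-phosphoglycerol "LTA primer" DAG-Glc-Glc-P-Gro, and its
mono- and di-alanylated forms) can be identified in polar lipid extracts by
tandem MS, provided their exact masses and fragment ions can be predicted
and matched. `ltafrag` is aimed at lipidomics analysts doing exactly that.

The package provides:

* **Exact-mass arithmetic** — Hill-notation formula parsing, monoisotopic
  and nominal masses, condensation arithmetic, and the adduct conventions
  [M+Na]⁺ (sodium-atom mass), [M−H]⁻ and [M−2H]²⁻ (proton mass, 1.007276).
* **A lipid shorthand parser** — `"(30:0) DAG-Glc-Glc-P-Gro-Ala"`,
  `"(15:0/17:0) PG"`, `"(60:0) CL"`, with formula and precursor m/z for
  every species.
* **A rule-based fragmenter** — theoretical fragment catalogs produced by
  cutting up to three labelled scissile bonds of the residue graph, with
  explicit water bookkeeping per cut (the `- H` / `- H3O` / `- H5O2`
  family), an allylic double-acid-loss channel, and the two rearrangement
  ions unique to the di-alanylated primer (Ala-Ala − H at 159.0775 and
  M − CO₂ − H).
* **A spectrum annotator** — greedy nearest-match annotation of MGF/CSV
  peak lists within an absolute tolerance, precursor-ion-scan emulation,
  and species nomination from a precursor m/z plus one of the three
  diagnostic ions (347⁺ sodiated dehydrated diglucose, 153⁻ cyclic
  glycerophosphate, 88⁻ deprotonated alanine).
* **A seeded synthetic-spectrum generator** — MS/MS spectra, mixture full
  scans and precursor-scan traces with configurable m/z error and noise,
  including a default *B. subtilis* membrane mixture.
* **A CLI** — `inst/cli/ltafrag` with `fragments`, `annotate`, `scan` and
  `simulate` subcommands over the same functions.

## Worked example

Parse the (30:0) LTA primer, enumerate its negative-mode catalog, and
annotate the transcribed reference peak list:

```r
library(ltafrag)

sp <- parse_species("(30:0) DAG-Glc-Glc-P-Gro")
sp
#> <lipid species> (30:0) DAG-Glc-Glc-P-Gro
#>   class:    LTA_primer
#>   chains:   15:0, 15:0  (default split of unresolved sum)
#>   formula:  C48H91O20P
#>   precursor: 1017.5769 (deprotonated_anion)

tab <- reference_fragment_table(2)     # transcribed observed peak list
obs <- mass_spectrum(tab$observed, rep(1, nrow(tab)), "negative",
                     precursor_mz = 1017.577)
annotate_spectrum(obs, sp, tol = 0.01)
#> <annotation> (30:0) DAG-Glc-Glc-P-Gro: 12/12 peaks matched (tol 0.01 amu)
#>   max |delta| 0.00978 amu, mean |delta| 0.00245 amu
#>      peak_mz   mz_calc   delta cleavage                    description
#> 1    78.9589   78.9591 -0.0002    g & i                        P - H3O
#> 2   152.9959  152.9958  0.0001        h                    P-Gro - H3O
#> 3   171.0062  171.0064 -0.0002        g                      P-Gro - H
#> 4   241.2171  241.2173 -0.0002       b1                  (15:0) FA - H
#> ...
#> 12 1017.5769 1017.5769  0.0000        M                (30:0) LTAP - H
```

Every observed fragment of the primer is explained: the phosphate and
cyclic/linear glycerophosphate ions (79/153/171), the dominant (15:0) fatty
acid anion (241), the glycosyl-bond fragments (315/477), the paired
acid/ketene losses (701/719 and 775/793), the cycloglycerol loss (943) and
the molecular anion (1017.577).

Nominating a species from the 153⁻ precursor scan hit at 1017.58:

```r
nominate_species(1017.58, "phosphoglycerol_153", tol = 0.02)[1, ]
#>                    species      class carbons double_bonds  mz_calc    delta
#> 1 (30:0) DAG-Glc-Glc-P-Gro LTA_primer      30            0 1017.577 -0.00314
```

And the 88⁻ scan of the default membrane mixture shows the alanyl-PG
cluster plus the two alanylated-primer clusters 71 amu apart:

```r
tr <- simulate_precursor_scan(bsubtilis_mixture(), "alaninate_88",
                              noise = noise_model(seed = 7))
round(sort(tr$peaks$mz))
#> [1]  765  793 1089 1117 1160 1188
```

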
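Package: ltafrag
Title: In-Silico Fragmentation and Annotation of Lipoteichoic Acid Primer Lipids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the glycolipid anchor, the lipoteichoic acid
    (LTA) primer and its mono- and di-alanylated derivatives of Bacillus
    subtilis in direct-infusion tandem mass spectra. Provides exact
    molecular-formula arithmetic with monoisotopic and nominal masses, a
    shorthand parser for diacylglycerol-diglucose-phosphoglycerol-alanine
    lipid species, a rule-based fragmenter that enumerates theoretical
    fragment ions by cutting labelled scissile bonds with explicit water
    bookkeeping (including allylic and rearrangement channels), a spectrum
    annotator with emulation of the diagnostic 347+/153-/88- precursor-ion
    scans, and a seeded synthetic-spectrum generator so the whole pipeline is
    testable without instrument data. Reads and writes MGF and two-column CSV
    peak lists and exports tab-separated fragment catalogs and annotation
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
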
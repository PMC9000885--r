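Package: flavotier
Title: Multi-Tiered Tandem Mass Spectrometry Annotation of Flavonoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for confidence-tiered annotation of flavonoid MS/MS spectra in
    positive ion mode. Implements monoisotopic formula arithmetic and CHO formula
    decomposition, MSP/MGF peak-list input and output, normalized dot-product and
    spectral-entropy similarity, retro-Diels-Alder fragment calculators for twelve
    flavonoid subclasses, machine-checkable subclass fragmentation rules,
    neutral-loss fragmentation trees, and a pipeline that assigns Schymanski
    confidence levels (1, 2a, 2b, 3, 4, 5) from reference-standard matches,
    spectral-library search, in-silico bond-breaking candidate ranking and de novo
    formula annotation. A seeded synthetic spectrum generator reproduces the
    diagnostic fragment content of each subclass for benchmarking without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
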
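Package: mscsa
Title: Composite Spectra Analysis and Entropy-Based Annotation for
    Untargeted LC/HRMS Metabolomics
Version: 0.1.0
Authors@R:
    person("mscsa", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deconvolutes co-eluting MS1 ion clusters into composite
    spectra (CSA) by correlating smoothed extracted-ion chromatograms,
    extracts DDA and DIA fragmentation spectra, aggregates recurring
    spectral variants across samples, and annotates spectra against MSP
    and MGF libraries using cosine similarity, spectral entropy
    similarity, and normalized Euclidean mass error.  Includes a minimal
    centroided mzML reader/writer, a versioned fragmentation-spectra
    database (FSDB) with cached entropies and characteristic markers, a
    ground-truthed synthetic fixture generator, and a single-command
    workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
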
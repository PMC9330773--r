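Package: lcmsmatch
Title: MS/MS-Seeded Peak Grouping and Spectral Library Matching for DDA LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless pipeline for annotating data-dependent acquisition
    (DDA) LC-MS/MS runs by spectral library matching. MS2 scans seed
    (m/z, retention time) slices that are merged and used for extracted-ion
    chromatogram peak detection and cross-sample peak grouping; MS2 scans
    assigned to each peak group are combined into a consensus spectrum and
    searched against spectral libraries (NIST msp, CSV, or an SQLite store)
    with five similarity scores, including a hypergeometric match score that
    is robust to chimeric spectra. Also includes a rule-based in-silico lipid
    fragmentation library generator, a cross-library annotation concordance
    procedure built around the Retention Balance Point score threshold, and
    a deterministic synthetic-run generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    DBI,
    RSQLite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
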
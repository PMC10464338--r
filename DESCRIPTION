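Package: chsms
Title: Gradient Hexanediol Elution Proteomics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis for chromatin enriching hexanediol
    separation mass spectrometry (CHS-MS): label-free protein
    quantification tables from an isotonic-buffer control and gradient
    1,6-hexanediol (2%, 5%, 10%) elutions are filtered, imputed,
    quantile-normalized and Z-scored; per-protein hexanediol-vs-buffer
    abundance ratios, concentration shares and representative/common
    elution classes are computed; liquid-liquid phase separation relevant
    sequence features (low-complexity fraction via an entropy two-threshold
    detector, disorder fraction, fraction of charged residues, Uversky
    hydropathy) are derived from sequences; and class contrasts are tested
    with chi-square, t, Mann-Whitney and hypergeometric set-enrichment
    statistics with Benjamini-Hochberg correction. A synthetic-data
    generator with planted hexanediol-sensitivity classes makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    limma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
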
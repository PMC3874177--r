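Package: dsbquant
Title: Quantitative Comparison of Meiotic DSB Hotspots and Recombination
    Intermediates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare meiotic DNA double-strand-break (DSB) hotspots
    and recombination intermediates between two experimental conditions.
    Implements tiling-array ChIP signal normalization (median-normalized
    IP:WCE ratios) with cross-array calibration against reference hotspots,
    integration of probe signal over hotspot intervals, Southern-blot
    calibration to percent DNA breakage, differential calling by the 95%
    prediction interval of an ordinary least-squares comparison with
    replicate intersection and de novo hotspot detection, densitometry
    quantification of one-dimensional gel lanes (percent DNA broken,
    crossover DNA frequency) and two-dimensional gels (Holliday-junction
    frequency, intersister:interhomolog ratios), and recombination-genetics
    statistics (Haldane map function, summary t-tests, contingency
    chi-square).  A synthetic-data module generates array profiles, gel
    lanes, two-dimensional gels and cross outcomes with planted ground truth
    so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
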
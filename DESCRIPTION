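Package: rppaquant
Title: Quantification and Normalization of Reverse-Phase Protein Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw spot-level reverse-phase protein array (RPPA)
    quantification files into normalized relative protein concentrations.
    A single logistic response curve of intensity versus relative log2
    concentration is fitted jointly to all serial-dilution series on a
    slide, giving each sample series its position on the shared curve.
    Includes automatic slide-design inference from the first valid input
    file, optional spatial bias correction from technical-replicate
    control spots, a per-slide noise metric (standard deviation of
    technical-replicate concentration estimates), selectable protein
    loading normalization including an explicit no-normalization option,
    parallel per-slide batch processing with per-slide fault isolation,
    and a ground-truthed synthetic slide generator used for testing.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    minpack.lm,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
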
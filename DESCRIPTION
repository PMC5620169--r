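Package: cardimap
Title: Spatial Image-Omics Mapping of Left-Ventricular Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps per-location qPCR-derived gene-expression fold changes of
    the left ventricle onto 2D bulls-eye polar maps and 3D surface meshes,
    in the style of electroanatomical (NOGA) viability maps. Provides
    delta-delta-Ct relative quantification with geometric-mean reference
    normalization and standard-curve efficiency estimation, a 0-100 display
    transform with inverse-distance-weighted interpolation, AHA 17-segment
    assignment on the bulls-eye disk, ischemic/remote zone statistics with
    one-way ANOVA and Holm-Sidak step-down post-hoc adjustment, a 2xSD
    segmental relevance criterion, and a synthetic porcine
    ischemia/reperfusion study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
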
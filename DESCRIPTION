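Package: molarmorph
Title: 3D Landmark Geometric Morphometrics of Molar Crown Form
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics for 3D tooth crown
    analysis: file I/O for TPS, Morphologika-style and long-CSV landmark
    dialects, generalized Procrustes superimposition with tangent-space
    projection, hierarchical Procrustes ANOVA for measurement error,
    principal component analysis of shape with distance-correlation
    dimensionality selection, thin-plate-spline deformation grids, and a
    full hypothesis-testing battery (two-way ANOVA, Wilks-lambda
    MANOVA/MANCOVA with Rao's F, pairwise permutation tests with Holm
    correction, allometric regression, size correction and leave-one-out
    discriminant analysis). Includes a synthetic-study generator that
    emulates a four-group by two-sex clinical design with a replicated
    scan/digitization error hierarchy, and an end-to-end analysis
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
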
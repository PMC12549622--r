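Package: lensmech
Title: Coupled Analysis of Crystalline Lens Stiffness and Water Content
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the coupled analysis of crystalline lens biomechanics and
    hydration in spin-test / MRI experiments. Extracts axisymmetric lens geometry
    from silhouette images (aspheric cap fits with an equality-constrained cubic
    equatorial blend), computes lens thickness, equatorial diameter and
    solid-of-revolution volume, estimates a spatially varying shear modulus from
    spin-induced deformation by solving an inverse axisymmetric finite-element
    problem, maps free and total water from dual-flip-angle spoiled
    gradient-echo MRI with B1 correction, and compares regional profiles between
    treatment conditions. A synthetic-data generator provides ground-truth lens
    shapes, spun silhouette pairs and MRI phantoms for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    minpack.lm,
    lhs,
    EBImage,
    png,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, BiomedicalInformatics, Preprocessing
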
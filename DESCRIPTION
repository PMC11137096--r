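Package: vertemorph
Title: Statistical Shape Modelling and Hexahedral Mesh Morphing for the
    Thoracolumbar Spine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building statistical shape models (SSM) of families of
    corresponding anatomical surface meshes, morphing hexahedral finite-element
    templates onto them with coherent-point-drift (CPD) non-rigid registration,
    transferring SSM deformation fields to the hexahedral mesh, generating and
    annotating virtual cohorts of FE-ready spine models, and validating mesh
    quality (Jacobian ratio, aspect ratio, quad angles) and spinopelvic
    sagittal-balance parameters (PI, PT, SS, LL, GAP score). Includes readers
    and writers for STL surfaces and an Abaqus INP dialect subset, generalized
    Procrustes alignment, intervertebral-disc template construction with
    controlled nucleus/annulus proportions, and synthetic fixture generators
    for planted-mode shape families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
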
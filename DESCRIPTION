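Package: dmwasim
Title: Directional Microwave Ablation Simulation in Vertebral Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for directional microwave ablation (dMWA)
    in ex vivo vertebral bodies. Builds a voxelized vertebra phantom,
    deposits microwave power with a parametric directional line-source
    model calibrated against probe thermometry, solves the transient
    bioheat equation with an implicit finite-volume scheme, and provides
    virtual thermometry, ablation-extent measurement and the comparison
    statistics used to validate simulations against fiber-optic sensor
    logs. Includes a synthetic thermometry generator emulating probe
    placement uncertainty and sensor noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
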
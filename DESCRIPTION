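Package: tmjgap
Title: Automated Temporomandibular Joint Space Measurement from CBCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the radiological gap of the temporomandibular joint
    (TMJ) on cone-beam computed tomography (CBCT) volumes. The pipeline
    denoises a manually chosen volume of interest with a curvature-flow
    filter, segments the mandibular condyle on axial slices with a
    per-slice Gaussian mixture model, derives a uniquely defined vertical
    reference cross-section plane from the condyle's longest axial
    projection, and measures the upper, dorsal and frontal joint-space
    widths by intensity-profile and tangent-sweep analysis on the
    reference slice. A synthetic condyle/fossa phantom generator with
    analytically known gap widths makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
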
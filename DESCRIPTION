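Package: ctimaps
Title: Low-Frequency Brain Conductivity from Diffusion Microstructure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts fitted diffusion microstructure parameter maps (NODDI,
    SANDI and the spherical mean technique) into conductivity tensor imaging
    quantities (extracellular fraction and intra-/extracellular diffusivities),
    combines them with a modeled high-frequency conductivity atlas (Gabriel
    Cole-Cole dispersion evaluated at 128 MHz) to produce voxelwise effective
    low-frequency conductivity maps, and runs region-of-interest descriptive
    statistics with Wilcoxon signed-rank TOST equivalence testing between
    paired brain structures. Includes a reproducible synthetic multi-subject
    phantom generator (tissue-class atlas, lateralized ROIs, truncated-normal
    parameter maps) so the whole pipeline can be exercised without real
    diffusion MRI data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
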
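Package: MyelinPET
Title: Myelin Quantification from Dynamic Amyloid-Ligand PET with MR-Derived Lesion Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies white-matter myelin integrity from dynamic
    amyloid-ligand PET acquisitions of the kind used to study demyelination
    in multiple sclerosis. Implements supervised cluster analysis (SVCA) for
    data-driven reference-region extraction, voxelwise Logan graphical
    reference-tissue analysis producing distribution volume ratio (DVR)
    parametric maps, late-window standardized uptake value (SUV and SUVR)
    maps, lesion-centric mask algebra (normal-appearing white matter,
    perilesional rings, intralesional depth layers, resolution-based lesion
    filtering, and a DVR cutoff mask for impaired white matter), cerebral
    blood flow mapping from pseudo-continuous arterial spin labelling, and
    ROC/AUC discrimination analysis with the DeLong correlated-curve test.
    A digital dynamic-PET/MR phantom with known kinetic ground truth makes
    every stage testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    pracma,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
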
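Package: retveseg
Title: Retinal Blood Vessel Segmentation by Anisotropic Diffusion and
    Directional Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic segmentation of blood vessels in colour fundus
    photographs. The optic disc is located on the red channel by
    eight-neighbour Perona-Malik anisotropic diffusion followed by
    iterative mean-split (isodata) thresholding; the circular field of
    view is reconstructed from the green channel by binary morphology;
    vessels are enhanced by greyscale openings with twelve oriented line
    structuring elements, thresholded, and extracted with a disc top-hat,
    small-component removal and optic-disc exclusion. Includes pixel-wise
    sensitivity/specificity/accuracy evaluation against manual ground
    truth, DRIVE/STARE-style dataset readers, and a seeded synthetic
    fundus phantom generator with exact vessel, optic-disc and
    field-of-view masks so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    igraph,
    png,
    tiff,
    jpeg,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'imagery.R'
    'ppm.R'
    'diffusion.R'
    'thresholding.R'
    'morphology.R'
    'components.R'
    'od.R'
    'vessels.R'
    'evaluation.R'
    'phantom.R'
    'config.R'
    'retveseg-package.R'
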
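Package: myotrace
Title: Muscle Fiber Reconstruction from diceCT Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated reconstruction of muscle fascicle and fiber paths from
    diffusible iodine-based contrast-enhanced computed tomography (diceCT)
    image stacks. Starting from well-spaced seed points chosen by UPGMA
    clustering of bright pixels, a tracker walks forward and backward through
    the stack, at each step choosing the straight-line candidate path, over a
    spherical cap of voxel offsets, that minimizes the variation in grayscale
    values, optionally penalized for changes in trajectory. Raw stepwise
    tracks are smoothed with natural cubic splines, quality-filtered, fused
    and de-duplicated, and summarized as fiber length, orientation and
    tortuosity. Fiber sets can be rendered to static 3D figures and exported
    as STL tube meshes. A synthetic muscle-phantom generator with known fiber
    geometry supports validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    splines,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
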
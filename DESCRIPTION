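Package: teardrop
Title: Recurrent Neural Model of Figure-Ground Segregation by Medial-Axis Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A multi-layer recurrent rate model of figure-ground segregation
    in the primate ventral stream. Oriented edge energy is grouped by
    curvature-tuned contour cells at seven spatial scales, annular
    on-surround convex cells detect points along a figure's medial axis,
    and teardrop cells pool convex-cell activity along eight integration
    directions to measure boundary closure and gate sign-switching feedback
    that enhances activity inside figures and suppresses it outside.
    Includes parametric stimulus generators (rectangles, C-shapes, crosses,
    square textures, and seeded random-block figures), skeleton ground
    truth, lesionable feedback pathways, figure-ground indices, and a
    reproducible experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
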
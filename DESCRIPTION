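Package: lkmcpore
Title: Lattice Kinetic Monte Carlo Diffusion in Segmented Platelet Microstructures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts 2D segmentation imagery of platelet masses into binary
    pore/cell lattice domains, simulates hindered tracer diffusion on those
    domains with a next-reaction lattice kinetic Monte Carlo engine under
    mirror boundary conditions, and estimates long-time diffusion
    coefficients from ensemble mean-squared displacement. Includes
    brightness-threshold calibration of binarization against ground-truth
    masks by functional (diffusivity) agreement, staggered-subdomain
    diffusivity and porosity heatmaps, pore-width distributions via local
    thickness, and a synthetic generator of platelet-packing-like domains
    and emulated grayscale segmentation maps for fully self-contained
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
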
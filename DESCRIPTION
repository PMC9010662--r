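Package: photonmesh
Title: Tetrahedral-Mesh Monte Carlo Photon Transport for Tissue Optics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for mesh-based Monte Carlo simulation of light
    transport in turbid biological tissue. Builds labeled simulation domains from
    constructive geometry (boxes, layer cuts, cylinders, rough height-field
    interfaces) or from segmented 3-D volumes, tessellates them into
    region-tagged tetrahedral meshes with element-volume control, runs weighted
    photon-packet Monte Carlo transport (Henyey-Greenstein scattering, Fresnel
    boundaries, Russian roulette) to accumulate nodal fluence-rate maps, and
    exchanges all data through the JSON-based JMesh/JNIfTI mesh and volume
    formats, including typed and zlib-compressed array annotations. Also
    provides generators for randomized rough tissue interfaces quantified by the
    Ra roughness statistic and for hair-fiber geometry (random rooting, tilt,
    randomness, gravity bending) for downstream implicit Monte Carlo tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
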
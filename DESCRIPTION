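Package: surfmae
Title: Masked-Autoencoder Pretraining for Protein Surface Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds chemically annotated surface point clouds from protein
    structures (smooth-distance-function level-set sampling, multi-scale
    mean/Gaussian curvature, nearest-atom chemical features), pretrains a
    patch-based masked autoencoder over them with a chamfer reconstruction
    loss, and fine-tunes the pretrained encoder for binding-site
    identification, ligand-pocket classification and protein-protein
    interaction descriptor matching. Includes a synthetic protein-chain
    generator so the whole pipeline is testable without external data, and
    a small reverse-mode automatic-differentiation engine on which the
    transformer encoder, masked decoder and task heads are built.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
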
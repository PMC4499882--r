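Package: tfm3d
Title: Three-Dimensional Traction Force Microscopy for Collective Cell
    Migration in Collagen Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs matrix deformation, strain, and cell-generated
    traction from fiducial bead displacements in three-dimensional collagen
    gels, and quantifies the matrix remodeling and cohort dynamics that
    accompany collective epithelial migration. Bead trajectories referenced
    to a force-free state are interpolated into a continuous displacement
    field, differentiated into finite (Green-Lagrange) and infinitesimal
    strain tensors, and used as Dirichlet data for a linear-elastic finite
    element solve on a meshed gel domain from which Cauchy stress and
    interface tractions are extracted. Companion tools measure collagen
    fibril orientation from reflection-style images via the structure
    tensor with axial circular statistics, cross-correlate cohort shape
    dynamics with near- and far-field bead displacements, and build
    invasion-frequency maps and rose diagrams from binarized tissue masks.
    A synthetic-data layer generates every input with known ground truth
    (closed-form cavity and point-force elastic fields, Poisson bead
    seeding, fibrillar images, coupled time series, mask stacks) so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
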
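Package: cartstrain
Title: MRI-Based Glenohumeral Cartilage Strain Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pipeline for quantifying exercise-induced glenohumeral articular
    cartilage strain from segmented MRI contour stacks: surface reconstruction
    by contour lofting, rigid pre/post bone registration by iterative closest
    point, site-specific cartilage thickness maps by bone-vertex to nearest
    cartilage-vertex distance, 2-mm-radius anatomical sampling regions (18 on
    the humeral head, 9 on the glenoid), regional and compartmental compressive
    strain with repeated-measures statistics, and a synthetic shoulder phantom
    generator with known ground truth for end-to-end parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RANN,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
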
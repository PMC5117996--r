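Package: msemstitch
Title: Stitching and Web-Map Export for Multi-Beam Scanning Electron
    Microscopy Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs seamless gigapixel mosaics from multi-beam scanning
    electron microscopy (mSEM) acquisitions. Tiles are pairwise aligned by
    Fourier phase correlation, low-quality pairings are detected and replaced
    using per-overlap-type translation estimates, and the full tile set is
    globally registered by relaxing a damped mass-spring system (with sparse
    weighted least-squares reference solvers). Registered tiles are composited
    with feathered blending and exported as a 256x256 PNG tile pyramid for
    slippy-map viewers. Includes a synthetic acquisition generator with known
    ground truth (hexagonal multi-beam fields of view, stage jitter,
    dark/blurred artifact regions) so the entire pipeline can be exercised and
    benchmarked without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml,
    withr
Config/testthat/edition: 3
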
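Package: cordshift
Title: Spinal Cord Dose Under Setup Errors and Neck Contour Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how regional neck setup errors and progressive body
    contour shrinkage change the spinal-cord near-maximum dose (D0.1cc) over a
    fractionated head-and-neck radiotherapy course, and implements a rapid
    estimation method that displaces the planned cord contour by the measured
    regional shift and re-reads the planned dose grid. Includes contour and
    mask geometry (slice surface areas, rasterization, regional partition of
    the cord), dose-volume metrics, longitudinal course summaries with
    head-versus-neck Wilcoxon comparisons and contour-change dose regression,
    a synthetic neck phantom with a declared toy depth-dose engine for
    end-to-end simulation, and readers for a versioned fixture format plus a
    minimal DICOM RTDOSE/RTSTRUCT subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
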
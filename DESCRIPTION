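Package: amapet
Title: Quantification of Aortic Sodium Fluoride PET Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify sodium fluoride PET uptake in the abdominal
    aorta from co-registered PET-CT volumes. Implements two measurement
    approaches: slice-wise tissue-to-background ratios (TBR) computed from
    3 mm trans-axial regions of interest, and centerline-based aortic
    microcalcification activity (AMA) with an upper-intensity threshold to
    suppress vertebral signal spill-over and a variable-radius volume of
    interest that tracks the changing aneurysm diameter. Includes the
    agreement and repeatability statistics used to compare such methods
    (Pearson correlation, two-way consistency intraclass correlation,
    Bland-Altman limits of agreement, coefficient of repeatability) and a
    digital phantom generator that produces co-registered PET/CT volumes of
    an aneurysmal aorta next to a hot vertebral column with known ground
    truth, so the full pipeline can be validated without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
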
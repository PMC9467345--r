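Package: ccflow
Title: Choriocapillaris Flow-Void Quantification from En Face OCTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies choriocapillaris flow deficits from en face optical
    coherence tomography angiography (OCTA). Implements multi-frame rigid
    registration and averaging of 3 x 3 mm choriocapillaris frames guided by
    superficial-capillary-plexus reference images, Phansalkar local adaptive
    thresholding, connected-component flow-void metrics (count, total area,
    mean size), co-localization of flow voids with dark pachyvessel lumens on
    choroidal en face OCT, and the cohort statistics used to compare
    pachychoroid pigment epitheliopathy eyes against controls (unpaired
    t-tests from raw data or summary statistics, chi-square tests, Pearson
    and partial correlation adjusting for age and sex). A ground-truthed
    synthetic-image generator emulates speckled OCTA frame stacks over a
    capillary meshwork, choroidal vessel images, and cohort tables so the
    whole pipeline is testable without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
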
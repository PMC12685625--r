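Package: nwuct
Title: Densitometric Net Water Uptake from Serial Non-Contrast Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ischemic cerebral edema on serial non-contrast head CT
    as net water uptake (NWU): follow-up scans are affinely registered to
    baseline and to a symmetric reference atlas, lesion segmentations are
    mirrored across the midsagittal plane to define a contralateral reference
    region, a 20-80 Hounsfield-unit band is applied, hemorrhagic voxels are
    excluded, and NWU is computed as one minus the ratio of mean lesion to
    mean reference density. Includes synthetic head-CT phantoms with known
    water uptake and a cohort simulator with a known regression structure,
    baseline-adjusted change-score regression of edema progression on
    thrombolysis and reperfusion status, chained-equations imputation with
    Rubin pooling, and cohort descriptive tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
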
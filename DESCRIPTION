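Package: mrmpick
Title: Automatic Peak Picking and Reporting for MRM Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automatic preprocessing of targeted LC-QQQ-MS data acquired
    in multiple reaction monitoring (MRM) mode. Detects candidate peaks on
    smoothed quantifier traces, characterises them with a 20-element vector of
    chromatographic quality scores, aligns retention times across samples with
    a two-pass cross-correlation scheme regularised by a quadratic drift model,
    integrates peaks on a summed prototype chromatogram with border
    propagation, and gates reported peaks with a second classifier. Includes
    the training workflow for both the peak-picking and the peak-reporting
    classifiers, a synthetic MRM batch generator with known ground truth, and
    evaluation instruments (confusion metrics, replicate variability,
    correlation to reference values).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    e1071,
    mzR,
    nnet,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
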
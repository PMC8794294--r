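Package: nirspipe
Title: Intraoperative fNIRS Analysis of Nociception Under General Anesthesia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multichannel continuous-wave functional
    near-infrared spectroscopy (fNIRS) recorded during surgery under general
    anesthesia. Converts dual-wavelength optode intensities to oxy-, deoxy-
    and total-hemoglobin concentration changes (modified Beer-Lambert law)
    with wavelet motion correction, band-pass filtering, short-separation
    nuisance regression and polynomial detrending; extracts event-locked
    60-s epochs around painful surgical procedures and a procedure-free
    baseline; computes standardized rolling-average response curves,
    absolute area-under-curve nociception metrics and sliding-window
    region-to-region correlations; and compares nerve-block versus
    no-nerve-block groups with split-plot mixed ANOVA, two-sample t-tests
    and Benjamini-Hochberg false-discovery-rate control. Includes a seeded
    synthetic intraoperative-session generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    data.table,
    yaml,
    rlang,
    tibble,
    dplyr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    sandwich,
    lmtest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
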
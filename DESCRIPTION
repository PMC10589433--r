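Package: cvrsvd
Title: Cerebrovascular Reactivity Estimation and Small Vessel Disease
    Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates blood-oxygen-level-dependent (BOLD) cerebrovascular
    reactivity (CVR, in percent signal change per mmHg end-tidal CO2) from
    a hypercapnia gas-challenge acquisition, using a delay-optimized
    end-tidal CO2 regressor with a linear drift term and region-of-interest
    mean time series extracted from morphologically conditioned tissue
    masks (subcortical grey matter, normal-appearing white matter, white
    matter hyperintensities). Relates CVR to small-vessel-disease imaging
    features and cognition through covariate-adjusted linear regressions,
    paired inter-region contrasts and standardized coefficients. Includes
    a synthetic-data module (gas paradigms, end-tidal CO2 traces, BOLD
    series, phantom mask volumes and cohort tables with known ground
    truth) so that every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
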
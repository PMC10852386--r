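Package: outagecc
Title: Case-Crossover Analysis of Power-Outage Exposure and Pediatric Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the association between electrical power
    outages and acute hospitalizations with a time-stratified case-crossover
    design. Builds thresholded, windowed cumulative outage-hour exposure
    metrics from sub-county 30-minute outage feeds, quality-filters reporting
    units, links census block groups to outage units by population centroid,
    classifies urbanicity by areally interpolated rural population share,
    resolves ICD-10 external-cause codes to injury categories with
    most-specific-code tie-breaking, matches referent times on hour of
    admission, day of week, month and year, and fits conditional logistic
    regression by Newton-Raphson on the matched-set likelihood. A synthetic
    data generator with a known true exposure effect supports end-to-end
    testing and parameter-recovery studies without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    splines
Config/testthat/edition: 3
RoxygenNote: 7.3.3
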
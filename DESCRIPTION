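Package: fallfusion
Title: Wearable-Sensor Fall Detection Algorithms and Their Statistical Comparison
Version: 0.1.0
Authors@R:
    person("fallfusion", "developers", email = "fallfusion@example.org",
           role = c("aut", "cre"))
Description: Implementations of four fall-detection algorithms for waist- or
    pocket-worn inertial measurement units (IMUs): a two-phase free-fall/impact
    threshold detector on acceleration magnitude and complementary-filter
    vertical acceleration; a five-feature sliding-window threshold cascade
    fusing accelerometer and gyroscope statistics; a correlation detector
    matching 5 s activity patterns with gyroscope refinement; and a finite
    state machine candidate detector followed by a k-nearest-neighbour
    classifier on time- and frequency-domain features. The package also
    provides the supporting experimental protocol: stratified 10-fold
    cross-validation with random threshold search and ROC-distance selection,
    confusion-matrix performance metrics, the Friedman rank test in its
    two-way-with-replication ANOVA table form, the Nemenyi post-hoc test, and
    a seeded synthetic generator of fall and activity-of-daily-living IMU
    recordings so the whole comparison pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
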
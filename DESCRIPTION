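Package: freshnose
Title: Electronic-Nose Freshness Grading with a GA-Optimised Backpropagation Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intelligent freshness evaluation of chilled seafood from
    metal-oxide gas-sensor (electronic nose) arrays. Implements spoilage-index
    grading rules (total volatile basic nitrogen, total plate count, sensory
    score), internal-standard quantification of dimethyl sulfide from GC-MS peak
    areas, min-max normalisation and principal-component reduction of 10-channel
    sensor data, Euclidean-distance clustering and loading-angle analysis of
    quality indices, and a three-class feed-forward neural network whose initial
    weights and thresholds are found by a real-coded genetic algorithm before
    backpropagation training. A synthetic electronic-nose data generator
    reproduces the statistical structure of storage trials at four temperatures
    so the whole pipeline is testable without instrument recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
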
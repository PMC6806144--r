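Package: lychee
Title: Detection of Overlapped Lychee Fruits in Orchard Images
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monocular-vision detection of lychee fruits in orchard-style RGB
    images. Implements illumination compensation by contrast-limited adaptive
    histogram equalization (CLAHE) on the HSV value channel, foreground
    extraction by relative red-blue chromatic mapping with Otsu thresholding
    and morphological cleanup, a topological status classifier that labels
    each foreground region isolated, occluded or overlapped by comparing its
    Hough circles against its equivalent foreground area circle, a
    polar-coordinate extreme-value procedure that splits overlapped fruit
    clusters into individual circles through min-max-min extremum triplets and
    the three-point circumcircle, and a uniform local binary pattern texture
    filter classified by a histogram-intersection-kernel support vector
    machine. Ships a seeded synthetic orchard-scene generator with exact
    ground truth so every pipeline stage is testable without field data, plus
    detection metrics (precision, recall, F1) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
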
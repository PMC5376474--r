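Package: histmerge
Title: Multilevel Thresholding of Grayscale Images by Histogram Region Merging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multithreshold segmentation of 8-bit grayscale images by greedy
    histogram region merging: all 256 gray levels start as singleton regions
    and, at each iteration, the region with minimum energy D = omega * sigma^2
    (probability mass times within-region gray variance) is merged into the
    lower-energy adjacent region, removing one threshold per step until the
    requested number of thresholds remains. The number of iterations is
    bounded by 255 regardless of the threshold count, so the cost is linear in
    the number of gray levels. Ships with an exhaustive multilevel Otsu
    comparator (compiled search over all threshold tuples up to four
    thresholds), a segmentation uniformity index, a Gaussian-mixture
    synthetic-image generator with analytic ground-truth valleys for
    benchmarking on MR-like intensity distributions, and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
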
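Package: mutstage
Title: Stem-Cell Mutation Accumulation and Multistage Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the accumulation of somatic mutations in a stem-cell pool
    that grows exponentially to a fixed capacity and is then maintained by
    turnover. Replication errors arise at division (Poisson, mean lambda1)
    and mutagen-induced lesions arise independently of division (Poisson,
    mean lambda2 per cell per time). Provides an exact Gillespie simulator of
    the two-phase process, closed-form approximations for divisions, errors
    and lesions, a multistage carcinogenesis risk function on the accumulated
    mutation burden, least-squares fitting of age versus cumulative cancer
    risk curves to estimate the number of driver genes and the driver
    mutation rate per division, risk-difference analysis of mutagen
    influence, and a synthetic registry-style data generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
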
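Package: genoprof
Title: Genome Profiling Species Classification from Spiddos Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of the genome profiling (GP) approach to
    species classification. Normalizes temperature gradient gel
    electrophoresis (TGGE) feature points into species identification dots
    (spiddos), computes the pattern similarity score (PaSS) between genome
    profiles by optimal matching of their feature points, builds genome
    distance matrices (d_G = 1 - PaSS), clusters them with the
    Lance-Williams agglomerative recurrence (Ward, group average, median),
    and quantifies agreement between dendrograms with the cluster matching
    score (CMS), the congruence value Vc and its coarse-grained variant
    Vc'. Includes a synthetic-profile simulator that evolves spiddos along
    a known ultrametric tree, a pipeline driver, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
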
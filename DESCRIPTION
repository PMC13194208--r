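Package: fragchange
Title: Multi-Scale Analysis of Forest Fragmentation Change Under Habitat Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether habitat loss makes landscapes more or less
    fragmented. Computes four class-level fragmentation measures (proportion of
    habitat, patch number, edge density, mean patch size) on binary habitat
    rasters within circular landscapes of multiple radii, a composite forest
    fragmentation index with Tukey-fence winsorization and min-max
    normalization, and per-landscape change classifications between two time
    points, summarized as outcome frequencies by landscape size, initial cover,
    loss magnitude, and biome. Includes a seeded neutral-landscape generator
    (spectral synthesis) and five parameterized habitat-loss scenarios so the
    whole pipeline runs on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
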
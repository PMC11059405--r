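Package: irmap
Title: Climate-Driven Mapping of Insecticide Resistance Risk in Malaria Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental susceptible-resistant-offspring (S-R-M) models of
    insecticide resistance transmission in Anopheles gambiae populations, a
    basic reproduction number for resistance driven by temperature-dependent
    mosquito mortality and rainfall/temperature-dependent oviposition, local
    (perturbation) and global (Latin hypercube + partial rank correlation)
    sensitivity analysis, and a raster pipeline that turns monthly climate
    grids into per-pixel R0 risk maps, 95 percent confidence-interval layers,
    and point-overlay validation statistics. Includes a seeded synthetic
    climate and observation-point generator so the full pipeline runs with no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
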
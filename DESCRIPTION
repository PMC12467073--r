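Package: ratework
Title: Rate-Dependent Work-Energy Partitioning in Viscoelastic Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates how loading rate partitions mechanical work between
    recoverable elastic storage and irreversible viscous dissipation in
    soft biological systems. Implements the Kelvin-Voigt viscoelastic
    force law with optional adhesion, the Hill muscle force-velocity
    relation and its work per contraction, linear displacement ramp
    protocols with trapezoidal work integration, and builders for
    nanoparticle-membrane indentation scenarios across particle sizes and
    entry speeds. Results are tidy tibbles with broom-style tidiers and
    ggplot2 plotting helpers; a small command-line interface reproduces
    the reference energy tables and force/work traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
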
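Package: sfma
Title: Prioritized Hippocampal Replay Simulation in Grid Worlds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates hippocampal replay as stochastic prioritized
    reactivation of stored experience tuples, driven by experience strength,
    structure-aware state similarity (the Default Representation with
    low-rank barrier updates) and inhibition of return. Includes grid-world
    environments, a tabular Q-learning agent trained from replay, replay
    statistics (Brownian diffusion analysis, directionality, template
    matching for shortcut and preplay detection, reactivation maps) and
    runners reproducing the full set of simulation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    purrr
Config/testthat/edition: 3
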
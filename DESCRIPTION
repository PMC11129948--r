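Package: copytask
Title: Decompose Continuous Object-Copying Behaviour into Cognitive Subcomponents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting frame-by-frame behavioural logs from an
    immersive object-copying task into cognitive subcomponents: encoding
    periods on a model display, visual-search periods in a resource pool,
    working-memory usage sequences, sensorimnemonic (memory-versus-sampling)
    decisions, and identity/location errors. Includes a generative task-agent
    simulator that emits frame logs with ground-truth annotations so every
    detector can be validated by parameter recovery, plus tidy summary tables
    and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
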
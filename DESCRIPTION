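Package: gaitbouts
Title: Walking-Bout Detection from Shank-Worn Gyroscopes with Personalized Thresholds
Version: 0.1.0
Authors@R: person("gaitbouts", "developers", role = c("aut", "cre"),
    email = "gaitbouts@example.org")
Description: Detects walking bouts from shank-worn gyroscope recordings by
    locating midswing peaks on the pitch angular velocity and grouping them
    into alternating left/right sequences under four timing/amplitude
    thresholds. Provides population-level and individual-level threshold
    customization from supervised laboratory gait trials, evaluation against
    interval activity labels with a temporal tolerance, walking-speed
    distribution statistics, a ground-truthed synthetic gait simulator, and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
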
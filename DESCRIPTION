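Package: homecage
Title: Analysis of Group-Housed Home-Cage Drinking and Social Behavior
Version: 0.1.0
Authors@R: person("Home-Cage", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing event logs from sensor-equipped group
    housing cages in which individually tagged mice visit corners, perform
    nose pokes and lick bottles. Provides a canonical tab-separated event
    dialect with validation, machine-readable access schedules (intermittent
    two-bottle alcohol access, quinine adulteration, progressive-ratio and
    punishment-risk contingencies), per-animal drinking and activity metrics
    (preference ratio, bottle-side bias, circadian profiles, intake and dose
    conversion), progressive-ratio breakpoint extraction, and a
    permutation-null inference of follow/avoid relationships from corner
    entry sequences. Includes an agent-based cohort simulator that generates
    event logs with the statistical structure the analyses assume, so every
    stage can be tested without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
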
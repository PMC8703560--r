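Package: greenlight
Title: Optimal and Predictive Supplemental Lighting Control for Greenhouses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cost-optimal supplemental LED lighting control in
    greenhouses. A receding-horizon convex optimizer schedules per-step LED
    electron transport rate so that the crop's daily photochemical integral
    (DPI) target is met at minimum electricity cost under time-of-use
    pricing, using a Markov-chain forecast of the remaining day's sunlight.
    Includes the exponential-saturation ETR-PPFD light-response model,
    a seeded synthetic greenhouse irradiance generator, a price- and
    forecast-blind threshold heuristic, and a perfect-knowledge baseline
    for benchmarking daily and seasonal lighting cost.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
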
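Package: fiveaday
Title: Diet Optimization and Health Impact Modelling for Fruit and
    Vegetable Consumption Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models national consumption pathways to the UK "5-a-day"
    fruit and vegetable recommendation. A baseline national-average diet is
    optimized by linear programming into four pathway diets (fruit-and-
    vegetable or vegetable-only increases, all varieties or UK-capable
    varieties), with additional fruit replacing sweet snacks and additional
    vegetables replacing meat on a per-kilocalorie basis under a fixed
    dietary-energy constraint. Health impacts are quantified with a
    sex-specific life-table engine using lagged, multiplicative, log-linear
    relative risks for six disease endpoints; greenhouse-gas emissions, blue
    water footprints and diet cost are accounted at per-capita and national
    scale. A seedable synthetic-data module generates food-group, trade-share
    and population inputs with the statistical structure of the national
    dietary survey data, including a calibrated baseline fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
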
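Package: dmcua
Title: Diabetes Microsimulation for Cost-Utility Analysis and Value-Based
    Price Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-level semi-Markov microsimulation of long-term type 2
    diabetes outcomes driving cost-utility analysis from a healthcare
    provider's perspective.  Generates synthetic baseline cohorts from
    published summary statistics, evolves risk factors and annual
    complication/mortality events through configurable UKPDS-style risk
    equations, accrues discounted costs and quality-adjusted life years,
    and classifies incremental cost-utility ratios against
    willingness-to-pay thresholds.  Includes a binary-search inversion of
    the incremental cost-utility ratio to find the annual drug price that
    meets a willingness-to-pay target, plus one-way (tornado),
    probabilistic and scenario sensitivity analyses, all under common
    random numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'cohort.R'
    'risk.R'
    'microsim.R'
    'econ.R'
    'defaults.R'
    'config.R'
    'cua.R'
    'price.R'
    'sensitivity.R'
    'pipeline.R'
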
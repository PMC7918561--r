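Package: graysys
Title: Gray System Models for Health Expenditure Analysis and Forecasting
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gray (grey) system tools for small-sample annual time series,
    built around the analysis of China's total health expenditure and its
    driving factors over 2000-2018. Implements gray relational analysis for
    ranking driving factors, the univariate GM(1,1) and multivariate GM(1,N)
    gray forecasting models, and the new-structure multivariate gray model
    NSGM(1,N) with a linear correction term and gray action. Includes the
    study panel as a built-in fixture, a train/test evaluation protocol with
    residual-percentage reporting, descriptive health-financing statistics,
    and generators for difference-equation-consistent synthetic panels used
    in parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
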
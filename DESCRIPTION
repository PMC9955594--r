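Package: castvote
Title: Casting Voters and Optimal Sequential Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models sequential binary decision-making in groups where each
    respondent privately guesses (a "primary choice" correct with probability
    equal to their ability), observes the public answers of all earlier
    respondents, and answers so as to maximise their own probability of being
    correct. Implements the recursive casting-voter identification algorithm,
    log-odds likelihood aggregation over casting voters, exact enumeration of
    mean performance, closed-form results for equal-ability chains, a single
    expert among equals, and the complete three-person case analysis, plus a
    seeded Monte-Carlo simulator of decision chains. Baselines for
    simultaneous (independent) voting include weighted-majority optimality
    checks, Condorcet majority accuracy, and the effective number of voters.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
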
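Package: posnerrt
Title: Bayesian Observer and Evolved Spiking-Network Models of the Posner Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for simple and choice reaction-time (SRT/CRT) versions
    of the Posner spatial-cueing task. A sensory model implements Bayesian
    sequential detection of a noisy target with cue-dependent spatial priors
    and a posterior-probability response threshold, reproducing cue-validity
    effects, the speed-accuracy trade-off, and anticipation/commission error
    rates. A motor model evolves small fully connected leaky integrate-and-fire
    networks with an island-model genetic algorithm (elitism, tournament
    selection, uniform crossover, bounded mutation, periodic migration),
    reproducing relative-frequency effects and noise-limited reaction times.
    Results are returned as tibbles with broom-style tidy()/glance() methods
    and ggplot2 plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
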
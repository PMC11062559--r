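Package: specrel
Title: Specificity and Behavioural Relevance of Trial-Averaged Neural
    Population Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-part statistical test of whether trial-averaged neural
    population responses ("templates") are computationally meaningful. The
    Specificity Index measures, per trial, the excess Pearson correlation of a
    single-trial population vector to the template of its own experimental
    condition over the template of the alternative condition. The Behavioural
    Relevance Index compares Specificity between behaviourally correct and
    incorrect trials through the Vargha-Delaney A effect size derived from the
    Mann-Whitney U statistic. Includes two surrogate null generators (Gaussian
    resampling for calcium imaging, spike-count-conserving multinomial
    reallocation for electrophysiology), jackknife leave-one-neuron-out
    contribution analysis, neuron subsampling and trial clustering/grouping
    dissections, and a Poisson firing-rate simulator for mapping how
    selectivity spread, noise, and decision noise shape both metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
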
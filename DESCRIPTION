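Package: cllstrat
Title: Donor Stratification and Micropattern Motility Analysis for CLL T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-factor stratification of chronic lymphocytic leukemia (CLL)
    donors from mixed clinical and functional T-cell measurements, together
    with cell-motility metrics on micropatterned activating surfaces. Provides
    factor analysis of mixed data (FAMD) with an equal-contribution factor
    selection rule, chained-equation imputation with predictive mean matching,
    k-medoids grouping with elbow selection of the cluster number, resampling
    stability with cluster-label reconciliation, permutation Kruskal-Wallis
    and ANOVA/Tukey group statistics, and trajectory analysis (average speed,
    features crossed before stopping, time to stop) for cells migrating on
    square lattices of activating features. A synthetic-cohort generator with
    persistent-random-walk trajectories makes the full pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
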
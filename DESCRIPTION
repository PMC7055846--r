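Package: faunest
Title: Species Pool Richness Estimation for Biodiversity Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators of total species richness (the regional species pool)
    from multi-site biodiversity inventory data, such as Malaise trap surveys.
    Implements a combined non-parametric estimator (CNE) that feeds Chao1-type
    within-site extrapolations of unique and duplicate species counts into a
    Chao2-type across-site extrapolation, a Chapman mark-recapture estimator
    for faunas with a known prior species checklist, and a comparison suite of
    classical estimators (Chao1, ACE, Chao2, first- and second-order jackknife,
    bootstrap, Preston lognormal).  Includes delimited-text readers with the
    record-filtering rules used in large inventory projects, a synthetic
    community generator with site-occupancy heterogeneity, an estimator
    benchmarking framework based on log-scale error and species-pool coverage,
    species accumulation curves, and permutation tests for compositional
    trends across site groupings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), vegan, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
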
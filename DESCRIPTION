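Package: tomseek
Title: In Silico Discovery of Divergent TOM Complex Components
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of the comparative-genomics
    pipeline used to identify translocase of the outer membrane (TOM)
    components in organisms with highly divergent mitochondria, such as the
    hydrogenosomes of Trichomonas vaginalis. Provides profile hidden Markov
    model construction and local search with decoy-calibrated E-values,
    degenerate beta-signal motif scanning (PxGxxHxH), hydropathy-based
    transmembrane segment prediction and tail-anchor classification,
    label-free quantitative co-immunoprecipitation enrichment filtering,
    intersection triage against membrane proteomes, domain architecture
    classification (Hsp20-TPR-TMD), CLANS-style sequence similarity networks
    with force-directed layout, Dollo parsimony gain/loss mapping of
    presence/absence profiles on species trees, and seeded synthetic data
    generators that emulate each input so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    ape,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
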
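Package: cagmark
Title: Co-Abundance Group and Phenotype-Marker Analysis for Longitudinal Microbiome Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for 16S microbiome intervention studies run
    from finished OTU tables. Implements alpha diversity (Shannon, Simpson,
    Chao1, Faith's phylogenetic diversity, observed species), phylogenetic
    and correlation-based beta diversity (weighted/unweighted UniFrac,
    Spearman distances), principal coordinates analysis, one-way PERMANOVA
    with permutation p-values, Kruskal-Wallis with Dunn's post-hoc and
    Benjamini-Hochberg adjustment, paired Wilcoxon signed-rank tests with
    exact small-sample enumeration, co-abundance group (CAG) construction
    from Kendall correlations of mean temporal trends with Ward-D2
    clustering, and a random-forest importance procedure that discovers
    OTU markers of a continuous plasma phenotype such as ferric-reducing
    antioxidant power (FRAP). Ships seeded synthetic-data generators with
    exported ground truth for an in vitro colon-model arm and a
    longitudinal human feeding-study arm, plus end-to-end pipeline runners
    that emit tabular and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante,
    phangorn,
    phyloseq,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
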
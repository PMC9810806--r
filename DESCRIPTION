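Package: rotidiet
Title: Diet Selectivity Analysis for Gut-Content Versus Ambient-Water
    Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in-situ diet selectivity of a planktonic
    consumer from paired gut-content and ambient-water 18S metabarcoding
    OTU tables: consumer self-read removal, rank aggregation and relative
    abundance, exact hypergeometric rarefaction, shared/unique OTU
    accounting, Ivlev electivity index with preference classification,
    McNaughton dominance index, per-taxon gut-versus-water Wilcoxon tests
    with Benjamini-Hochberg FDR, Bray-Curtis dissimilarity, rank-based
    ANOSIM with effect-size banding, and environmentally constrained
    ordination (correspondence analysis, DCA axis-1 gradient length for
    the CCA-versus-RDA model choice, RDA, CCA) with Monte-Carlo
    permutation forward selection of environmental variables. Includes a
    synthetic-study generator producing paired gut/water tables with known
    ground-truth selectivity so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
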
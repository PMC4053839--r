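Package: methpair
Title: Pairing DNA Methylation Sites with Regulated Genes by Ranking
    Methylation-Expression Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairs CpG methylation sites with the genes they regulate by
    training a linear ranking model on promoter methylation-expression
    relationships across a panel of cell types, extrapolating the model to
    megabase-scale gene intervals to nominate distal enhancer sites, and
    quantifying how altered enhancer methylation tracks gene dysregulation
    in cancer. Includes variable-methylation-site filtering with iterative
    Thompson tau outlier rejection, hypergeometric minimum-rank query
    p-values, permutation enrichment of chromatin states and transcription
    factor binding, chromosome-conformation (5C) agreement statistics,
    normal-versus-cancer delta-methylation contrasts, and a synthetic-data
    generator that reproduces the statistical structure the analysis
    assumes so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
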
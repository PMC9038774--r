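Package: viromine
Title: Mining Soil Viromes for vOTUs, Host Links and Auxiliary Metabolic Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for soil virome mining from assembled
    metagenomic contigs: screening contigs for viral origin using VirSorter
    category gates and annotation-fraction criteria, greedy clustering into
    viral operational taxonomic units (vOTUs) at 95% nucleotide identity over
    80% coverage, majority-rules family-level taxonomy, virus-host linkage via
    shared tRNAs and CRISPR spacer/repeat evidence, partitioning of viral genes
    into core functional genes versus auxiliary metabolic genes (AMGs) with
    positional validation against viral hallmark genes, and the abundance,
    alpha/beta diversity and network statistics used to contrast clean and
    pesticide-contaminated soil communities. A synthetic-community generator
    produces complete datasets with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
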
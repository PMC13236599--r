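Package: evetrace
Title: Junction Resolution, Attachment-Site Profiling and Segregation
    Genetics of Latent Endogenous Giant Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing latent endogenous viral elements
    (EVEs) in algal genome assemblies: exact insertion-junction resolution
    against the EVE-free homologous chromosome with classification of the
    integration mechanism (recombinase core microhomology versus
    transposase target-site duplication), attachment-site (attB/attP/
    attL/attR) terminus profiling with position log-odds models and
    sequence logos, long-read detection of excision/circularization and
    hairpin-telomere (telRL) fold-back signatures, and Mendelian
    segregation and genotype-phenotype linkage statistics. A synthetic
    genome, long-read and meiotic-cross simulator provides ground-truth
    inputs so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
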
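Package: ormine
Title: Olfactory Receptor Subgenome Mining and Phylogenetic Comparative
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines olfactory receptor (OR) gene repertoires from genome
    assemblies and analyses their evolution across species. Builds
    per-family amino-acid profile models from seed coding sequences, scans
    assemblies by six-frame translated search, collapses redundant loci by
    greedy identity clustering, removes non-OR GPCRs with a per-candidate
    phylogenetic filter, and classifies each locus as functional, sub-7TM,
    or pseudogene using stop-codon, frameshift, length, and transmembrane-
    helix rules. Downstream tools aggregate per-species repertoire tables
    and implement phylogenetic comparative statistics: Pagel's lambda with
    likelihood-ratio tests, Brownian-motion and Ornstein-Uhlenbeck model
    fitting with information-criterion selection, phylogenetic Tukey
    contrasts, multivariate phylogenetic model comparison with MANOVA,
    ordination of normalized family proportions, and maximum-likelihood
    ancestral state reconstruction. A synthetic-data module generates
    ground-truthed genomes with planted OR genes and traits simulated under
    known evolutionary models for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    MASS,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    multcomp,
    jsonlite,
    withr
Config/testthat/edition: 3
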
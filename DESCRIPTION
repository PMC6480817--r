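Package: kdrhap
Title: Genotyping, Haplotype Phasing and Evolutionary Analysis of kdr
    Mutations in Aedes albopictus VGSC Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing knockdown-resistance (kdr) mutations in the
    voltage-gated sodium channel (VGSC) gene of Aedes albopictus from diploid
    Sanger amplicon sequencing. Implements amplicon reference models with
    Musca domestica codon numbering, a ground-truthed synthetic amplicon
    simulator, IUPAC-ambiguity diploid genotype calling via anchored
    alignment, rule-based haplotype phasing with clone cross-checking,
    population genotype and allele tabulation (including triple-locus
    genotype combinations), haplotype-origin inference by nearest wild
    neighbours, and Tamura-Nei (TN93) phylogenetics implemented from first
    principles: pairwise distances, neighbour-joining, pruning
    log-likelihood, NNI hill-climbing and bootstrap supports with Newick
    output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
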
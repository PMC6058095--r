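Package: stoichgen
Title: Stoichiogenomics of Marine Metagenomes: Protein Nitrogen
    Allocation Across Habitats, Membrane Topology and Evolutionary Rate
    Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores protein sequences for side-chain nitrogen content and
    compares nitrogen allocation between open-ocean and coastal microbial
    communities. Proteins are stratified by membrane topology (parsed from
    Phobius short-format predictions), by functional pathway (HMMER3 hit
    tables filtered at model noise cutoffs, assigned to the NtcA-induced
    nitrogen-starvation cascade or the arginine biosynthetic pathway), and
    by per-site evolutionary rate class estimated from scratch: masked
    alignment columns, Poisson-corrected protein distances, a
    neighbor-joining tree, and discrete-gamma empirical-Bayes posterior
    mean rates under the JTT substitution model, z-normalized and
    classified as slow, intermediate or fast. Group contrasts use
    rank-based tests (exact, normal-approximation and Monte-Carlo
    permutation variants). A seeded synthetic-data generator produces
    fully labeled studies (sequences, topologies, hit tables, gene-family
    alignments evolved along a known tree) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
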
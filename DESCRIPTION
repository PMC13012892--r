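Package: tcrgraphs
Title: Interface Graphs and Equivariant Classification of TCR-pMHC-I Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Residue-level interaction graphs for T-cell receptor (TCR) -
    peptide-MHC class I complexes built from PDB structures across five
    interface zones (MHC-peptide, peptide-TCRa, peptide-TCRb, MHC-TCRa,
    MHC-TCRb), with physicochemical, energetic and surface-derived node and
    edge features. Includes a variable-size graph VAE-GAN for generating
    weak-binding decoy interfaces with a three-level quality-control suite
    (feature Kullback-Leibler divergence, Weisfeiler-Lehman kernel maximum
    mean discrepancy, latent-space filtering), an equivariant graph neural
    network classifier of strong- versus weak-binding interactions, CDR-loop
    contact statistics, and a repeated stratified group-aware cross-validation
    protocol with feature-group ablation and a score-affinity mixture
    analysis. Synthetic complex and graph generators make every stage
    testable without external structural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
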
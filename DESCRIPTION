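Package: spdca
Title: Structure-Prior-Assisted Direct Coupling Analysis for
    Protein-Protein Interface Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts hot-spot peptide interfaces of protein heterodimers
    from paired ortholog alignments. Infers inter-protein evolutionary
    couplings with a pseudo-likelihood Potts model (plmDCA), convolves the
    inter-protein coupling map with a structure-prior Gaussian kernel to
    localise candidate interacting peptide rectangles, labels them with
    membrane-protein topology domains, profiles physicochemical properties
    at predicted interfaces, and provides trajectory validation criteria
    (Kabsch RMSD, radius of gyration, heavy-atom residue contact maps,
    native-contact fractions, and Debye-Hueckel screened electrostatic
    energies). A synthetic paired-alignment generator with planted
    inter-protein couplings makes the whole workflow testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Alignment, Software
RoxygenNote: 7.3.3
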
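Package: vhhforge
Title: Repertoire Statistics, CDR Annotation, Docking-Pose Clustering and
    Solubility Engineering for Single-Domain Antibodies
Version: 0.1.0
Authors@R:
    person("vhhforge", "maintainers", email = "vhhforge@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, ground-truthed toolbox for the computational side
    of nanobody (VHH) discovery campaigns. Generates synthetic VHH sequencing
    libraries and synthetic docked antibody-antigen pose ensembles with known
    cluster structure; estimates library diversity from the counts-of-counts
    (cardinality) spectrum by zero-truncated negative-binomial maximum
    likelihood; fits Gaussian length distributions; annotates CDR loops by
    framework anchor motifs; provides PDB input/output, Kabsch superposition,
    Shrake-Rupley accessible surface area and per-residue ensemble RMSD
    profiles; clusters docking decoys on an interface-RMSD matrix with DBSCAN
    (core/reachable/outlier labelling) after contact-based filtering; and
    flags exposed surface hydrophobics outside the CDRs for
    solubility-improving point mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
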
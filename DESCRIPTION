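Package: macrolib
Title: Combinatorial Enumeration and Profiling of Macrolide Scaffold Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-driven combinatorial assembly of macrocycle and
    macrolide (macrocyclic lactone) scaffolds from small backbone structural
    motifs with two attachment points. Builds very large, diversity-controlled
    virtual libraries by traversing the multiset-permutation space of the
    selected motifs with a configurable skip-sampling stride, closes each ring
    either directly or through an ester bridge (lactone), standardizes and
    deduplicates the resulting structures, and profiles libraries with
    drug-likeness descriptors (molecular weight, Wildman-Crippen SlogP, Ertl
    TPSA, hydrogen-bond donors/acceptors, rotatable bonds), Lipinski/Veber
    flags, descriptor correlation analysis, and MACCS-key Tanimoto similarity
    against probe macrolides. Exact big-integer accounting of the enumeration
    space and of sampling coverage is included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    tibble,
    stats,
    graphics,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
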
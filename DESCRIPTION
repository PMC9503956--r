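Package: dnassembly
Title: Template-Based Assembly of DNA Tertiary Structures from Secondary
    Structure Elements
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts all-atom three-dimensional structures of DNA from a
    sequence and an extended dot-bracket secondary structure.  The target is
    decomposed into smallest secondary elements (stems, hairpin, bulge,
    internal, junction, open and break loops), a 3D template is searched for
    each element in a fragment library built from experimental structures
    (with an RNA fallback and an ideal-geometry de novo builder), templates
    are assembled by Kabsch superposition on the two base pairs shared by
    adjoining elements, and imperfect assemblies are refined by a
    coarse-grained simulated-annealing Monte Carlo sampler scored with a
    knowledge-based statistical potential.  Includes tools to build and
    search template libraries, generate synthetic benchmark corpora, and
    evaluate predictions by all-atom RMSD with or without open loops.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
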
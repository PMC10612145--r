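Package: znbuffer
Title: Zinc Binding Thermodynamics, Speciation and Buffering of Metallothioneins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium-thermodynamics toolkit for Zn(II) binding to
    metallothioneins and other multi-site metalloproteins. Represents
    proteins by stepwise apparent dissociation constants (Adair models),
    solves multi-component Zn(II) mass-balance equilibria at fixed pH
    (proteins, 1:1 chelators, 1:1 fluorescent and 2:1 chromogenic probes),
    computes speciation profiles and zinc buffering windows, and implements
    the estimators that turn competition and titration data into constants:
    probe-competition dissociation models (PAR, ZnAF-2F), Hill fits of pH
    titrations and metal-buffer isotherms with chelator-depletion
    correction, manual-mode refinement of tight and moderate constants,
    pseudo-first-order DTNB oxidation kinetics, and titration endpoint
    detection. A synthetic-data generator emulates every supported
    experiment type with configurable Gaussian noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
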
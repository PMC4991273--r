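Package: flprobe
Title: Characterisation of Fluorescence-Lifetime DNA Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterising fluorescent dyes as
    G-quadruplex-selective fluorescence-lifetime probes. Implements
    time-correlated single-photon counting (TCSPC) multi-exponential
    iterative-reconvolution fitting with global (linked-lifetime) analysis
    and F-statistic support-plane accuracy intervals; steady-state emission
    titration analysis (fold enhancement, mole-ratio stoichiometry and
    exact 1:1 binding-motif association constants); cyclic-voltammetry
    midpoint-potential extraction with Rehm-Weller photoinduced
    electron-transfer energetics and thermodynamic-cycle redox potentials;
    coordinate-geometry utilities for conformational comparisons; and a
    synthetic-data generator that emulates the acquisition conditions with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
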
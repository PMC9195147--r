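Package: xasmelt
Title: X-Ray Absorption and Thermal-Denaturation Analysis of Protein Metal Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify divalent-metal binding to proteins from X-ray
    absorption spectra and circular-dichroism thermal scans. Implements
    Athena-style XANES edge-step normalization and pre-edge peak fitting,
    constrained two-component linear-combination fitting of bound versus
    free metal, AUTOBK-style spline background removal to extract the EXAFS
    fine structure chi(k), a single-scattering forward EXAFS model with
    rigid-group constrained refinement of shell distances and the Fermi
    energy shift, and melting-temperature extraction from the first
    derivative of ellipticity-vs-temperature scans. A synthetic-data module
    generates every input with known ground truth, and a pipeline driver
    joins the spectroscopic and thermal results into a stability report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    signal,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
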
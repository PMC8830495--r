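Package: amidesom
Title: Protein Secondary Structure from Amide I Infrared Spectra via
    Self-Organising Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates protein secondary-structure fractions (helix,
    beta-sheet, other) from Amide I infrared absorbance spectra using a
    Kohonen self-organising map trained on a reference set of proteins of
    known structure.  Includes leave-one-out validation, conversion between
    attenuated total reflectance (ATR) and transmission spectra, Fourier
    self-deconvolution, two Gaussian band-fitting estimators, spectral
    preprocessing (baselining, normalisation, scaled water subtraction),
    and a synthetic Amide I spectrum generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
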
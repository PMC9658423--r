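Package: anthostab
Title: Iron-Induced Color-Stability Indexes of Anthocyanin Extracts from
    UV-Vis and SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the color stability of anthocyanin extracts against
    ferric iron from paired UV-vis spectra (control versus iron-treated, at
    pH 3 and pH 6) as six stabilization indexes built from bathochromic and
    hyperchromic shifts, and links surface-enhanced Raman (SERS) spectra to
    those indexes by chemometrics: Savitzky-Golay second-derivative and
    standard-normal-variate preprocessing with spectral region selection,
    principal component analysis, and NIPALS PLS1 regression with
    leave-one-out cross-validation (PRESS/RMSECV), a stratified 75/25
    train/validation split (RMSEP, R squared), and loading-spectrum band
    diagnostics. Includes the pH-differential pigment quantitation, a
    synthetic study generator with known latent stability structure for
    end-to-end testing, and a scriptable pipeline with YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
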
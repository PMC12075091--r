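Package: aquaredox
Title: Redox-State Discrimination from Water NIR Spectra and
    Hydration-Shell Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric and trajectory-analysis workflows for identifying
    the redox state of thiol/disulfide couples (GSH/GSSG, NADH/NAD+) from
    the water first-overtone region of near-infrared spectra and from the
    hydration shell of the reactive sulfur site.  Implements difference
    spectra against a buffer background, region masking, standard normal
    variate and Savitzky-Golay preprocessing, PCA with Mahalanobis outlier
    screening, orthogonal signal correction, NIPALS partial least squares
    and principal component regression with leave-one-out and
    leave-k-spectra-out cross-validation, and regression-vector band
    localization.  A companion trajectory toolkit computes sulfur-water
    radial distribution functions, geometric hydrogen-bond detection with
    donor/acceptor directionality, residence intervals and
    residence-weighted interaction scores.  Seeded synthetic generators for
    spectra and solvation trajectories provide ground truth for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
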
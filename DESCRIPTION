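Package: amura
Title: Apparent q-Space Diffusion Metrics from Single-Shell Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes apparent q-space diffusion metrics (return-to-origin,
    return-to-plane and return-to-axis probabilities, propagator and diffusion
    anisotropy indices, and generalized q-space moments) from single-shell
    diffusion MRI under a mono-exponential radial decay model, together with
    classical diffusion-tensor scalars (FA, MD, AD, RD).  Includes a synthetic
    two-compartment (zeppelin plus free water) cohort generator with Rician
    noise and a toy white-matter atlas, skeleton-restricted trimmed ROI group
    statistics (pooled t-tests, Cohen's D, contingency chi-square), bootstrap
    subsampling of the group analysis across decreasing sample sizes with a
    majority-significance criterion, and stability analysis via the
    coefficient of quartile variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
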
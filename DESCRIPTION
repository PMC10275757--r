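Package: sonosim
Title: Focused-Ultrasound Field, Heating and Sonogenetic Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the biophysics and electrophysiology of focused
    ultrasound neurostimulation. Simulates the linear monochromatic pressure
    field of spherical-cap transducers (O'Neil closed form and Rayleigh
    surface integral), extracts beam metrics (focal-spot FWHM, peak depth)
    and acoustic exposure intensities (Isppa, Ispta, Isptp), builds the
    ultrasound heating source term and solves the Pennes bioheat equation
    for tissue temperature rise. Computes spike-train response metrics
    (spike density functions, latency, A/e duration, Fano factor,
    short/long-latency classes), spatial activation statistics for
    multi-electrode and micro-ECoG recordings (weighted dispersion, response
    centres, interpolated activation maps), and go/no-go licking-task
    behaviour metrics with robust outlier exclusion. Includes synthetic-data
    generators with ground-truth sidecars for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
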
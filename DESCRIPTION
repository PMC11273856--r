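Package: choromet
Title: Choroidal Morphometry and Stress-Session Analysis for OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying choroidal and retinal
    morphometry from swept-source optical coherence tomography (SS-OCT)
    volumes acquired in paired (baseline versus stressor) sessions, together
    with the accompanying heart-rate-variability and statistical analyses.
    Provides a ground-truthed synthetic OCT and RR-interval generator,
    per-B-scan enhancement (Perona-Malik anisotropic diffusion and
    column-wise adaptive attenuation compensation), rigid 3D volume
    registration and resampling, graph-search segmentation of the internal
    limiting membrane, mid-RPE and choroid-scleral interface, Bennett
    magnification scaling, fovea-centred region-of-interest thicknesses and
    directional best-fit-circle radii of the posterior eye, event-anchored
    mean heart rate and RMSSD, and a normality-gated paired testing,
    correlation and Bland-Altman battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
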
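Package: chemotaxr
Title: Single-Cell Chemotaxis Heterogeneity Analysis from Live-Cell Reporter Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying heterogeneous chemotaxis of
    single cells from multi-channel live-cell kinase translocation reporter
    (KTR) movies or per-cell track tables. Provides a ground-truthed synthetic
    data generator (oscillatory ERK/Akt signals, anti-phased aspect-ratio
    oscillations, polarization-gated speed bursts, advection-diffusion motion),
    nucleus-seeded segmentation and KTR quantification, Hungarian single-cell
    tracking with mitosis trimming, Fourier period-band decomposition of
    signaling amplitudes, heterogeneity statistics (quantile regression,
    top-quartile proportions, one-dimensional earth mover's distance), aligned
    aspect-ratio peak event analysis, and weak-form variational inference of
    population diffusivity (random migration) and advective velocity (directed
    motion) from density fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
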
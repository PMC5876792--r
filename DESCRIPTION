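Package: scatterid
Title: Differentiation of Optically Trapped Microparticles from
    Back-Scattered Signal Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for differentiating classes of optically
    trapped microparticles (no particle, PMMA, polystyrene, living yeast)
    from short epochs of a single-channel back-scattered photodetector
    signal. Provides a synthetic acquisition generator (amplitude-modulated
    1 kHz carrier with slow Nakagami-distributed envelope fluctuations),
    Butterworth high-pass preprocessing with z-score artifact rejection, a
    45-feature registry (time-domain statistics, Nakagami envelope fit,
    Hilbert-envelope DCT energy features, Haar/Db10 wavelet relative
    powers), a from-scratch Fisher linear discriminant solved as a
    generalized eigenproblem, and a nonparametric statistical layer
    (Kruskal-Wallis, pairwise Mann-Whitney, Bhattacharyya class
    separability, Spearman correlation of the discriminant score against
    the refractive-index contrast times diameter product).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
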
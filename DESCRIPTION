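Package: gibbonsong
Title: Individuality, Androgens and Age in Simulated Gibbon Solo Songs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a bioacoustic-endocrine analysis
    pipeline for male gibbon solo songs, driven end-to-end by a synthetic
    song generator with ground-truth annotations. Stages: frequency-modulated
    song synthesis with matched fecal androgen series; spectrogram-based
    element detection, fundamental-frequency contour measurement and call
    segmentation into 22 call-level acoustic parameters; varimax factor
    analysis with sampling-adequacy diagnostics and regression-method factor
    scores; a permuted discriminant function analysis (pDFA) whose
    significance respects the non-independence of calls recorded on the same
    day, via balanced call selections and day-wise restricted permutation;
    excretion-lag matching of fecal androgen measurements to recordings with
    within-subject centering; and Gaussian linear mixed models with a
    Gaussian-kernel residual temporal-autocorrelation covariate, Simes-adjusted
    p-values and leave-one-subject-out stability checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
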
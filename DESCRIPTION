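Package: valvegest
Title: Fetal Cardiac Valve Intervals and Gestational Age from Doppler
    Ultrasound and Fetal ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline that turns paired one-dimensional Doppler
    ultrasound (DUS) audio and noninvasive fetal ECG into per-beat cardiac
    valve events (mitral closing/opening, aortic opening/closing), the seven
    derived systolic and diastolic time intervals, fetal heart rate
    variability parameters, and a regression-based estimate of gestational
    age.  Includes signal-quality gating for both channels (bSQI for the
    fECG, a twelve-feature kernel-density Naive Bayes score for the DUS), a
    hybrid SVM-HMM valve-event decoder with constrained Viterbi search,
    stepwise gestational-age regression with leave-one-out cross-validation,
    Bland-Altman and threshold-sweep evaluation analytics, and a synthetic
    signal simulator with known ground truth so that every stage is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
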
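Package: emnav
Title: Color-Coded Electromagnetic Navigation for Mandibular Reconstruction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of a color-coded electromagnetic navigation
    pipeline for mandibular reconstruction with multi-segment fibular grafts:
    6-DOF pose algebra with explicit frame checking, streaming landmark
    acquisition with a stabilization-and-restart rule, paired-point rigid
    registration by Horn's quaternion method with fiducial and target
    registration error metrics, real-time point-cloud distance maps with
    color coding, a synthetic phantom and tracking simulator with known
    ground truth, and the postoperative accuracy statistics (mean +/- SD
    summaries, Pearson correlation, regression, Bland-Altman limits of
    agreement, Kolmogorov-Smirnov normality) for navigation-versus-CBCT
    agreement analysis.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
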
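Package: bsitools
Title: Adaptive Markov-Switching Decoding and Stimulation Control for a
    Brain-Spine Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, decoding and evaluation toolchain for a
    brain-spine interface that translates epidural electrocorticography
    (ECoG) into epidural spinal stimulation commands. Implements complex
    Morlet wavelet feature extraction on a 100 ms cadence, a recursive
    exponentially weighted Markov-switching multilinear decoder (hidden
    Markov gate plus per-state expert regressions with online
    calibration and progressive assistance), proportional and walking
    stimulation controllers with a 300 ms command cadence, recruitment
    curve calibration of stimulation program libraries, and the full set
    of evaluation statistics: delay-compensated decoding accuracy, EMG
    response accuracy, stepping probability profiles, resting-state
    signal stability, z-scored spectrograms, feature reinforcement,
    walking-model PCA stability and 26-parameter gait analysis. A fully
    seeded synthetic session generator provides co-registered ECoG,
    cues, EMG and kinematics with known ground truth.
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
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
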
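Package: wavesep
Title: Pressure-Only Aortic Wave Separation with Representative Flow Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for arterial wave separation analysis when no measured
    aortic flow waveform is available. Implements beat landmark detection,
    characteristic impedance estimation from the early-systolic
    pressure-flow relation, forward/backward pressure decomposition with
    reflection magnitude and centroid-method reflected-wave return time,
    construction and de-normalization of a population representative flow
    waveform, triangular flow synthesis, a virtual Doppler ultrasound
    simulator operating on cross-sectional velocity fields, and a
    tube-load synthetic hemodynamics generator with known ground-truth
    reflection for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
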
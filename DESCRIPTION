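Package: vsdqc
Title: Quality Metrics for Voltage-Sensitive Dye Recordings of the Pyloric
    Rhythm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the quality of voltage-sensitive dye (VSD)
    recordings of the crustacean pyloric central pattern generator. Implements
    burst detection and the standard pyloric pattern statistics (cycle period,
    burst duration, intraburst and instantaneous firing frequency, phase), the
    cycle-triggered signal-to-noise procedure for optical traces (sliding-mean
    DC removal, high-pass noise isolation, triggered averaging), photobleaching
    and dye-internalization quantification from 8-bit greyscale image stacks
    (mean grey values, luminosity histograms, exponential decay fits), and a
    frequency-band toxicity profile that scores deviation of the rhythm from a
    pre-dye control. A synthetic-data generator emulating triphasic pyloric
    activity, slow-wave plus spike fluorescence, photobleaching and membrane
    dye internalization makes every stage testable without raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
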
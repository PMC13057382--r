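Package: ventsync
Title: Patient-Ventilator Asynchrony Simulation, Detection and Crossover
    Trial Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying patient-ventilator asynchrony in
    spontaneously breathing pediatric patients on pressure support
    ventilation.  Simulates multichannel ventilator waveforms (airway
    pressure, flow, volume, esophageal pressure) from a single-compartment
    respiratory model with injectable asynchrony events and ground-truth
    logs; segments machine breaths and esophageal-pressure efforts;
    classifies auto-triggering, double breaths, ineffective efforts,
    trigger delay and early/late cycling from waveform criteria; computes
    the Asynchrony Index and related per-period outcomes; and provides the
    paired crossover statistics (Shapiro-Wilk routing, paired t /
    Wilcoxon signed-rank with Hodges-Lehmann median-difference intervals)
    and ARE-based Wilcoxon signed-rank power calculations used to design
    such trials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
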
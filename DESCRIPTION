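Package: murineEP
Title: Murine Cardiac Electrophysiology, Heart Rate Variability and
    Arrhythmia Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of murine cardiac electrophysiology across autonomic
    states: R-peak detection and ECG delineation with surface interval
    measurement (heart rate, PR, P duration, QRS, Mitchell-corrected QT),
    heart rate variability in the time domain, frequency domain (Lomb
    periodogram of the unevenly sampled tachogram with murine VLF/LF/HF
    bands) and Poincare plane, rule-based detection of sinus arrhythmia,
    Wenckebach and intermittent third-degree atrioventricular block and
    abnormal ventricular activity, extraction of programmed-stimulation
    parameters (corrected sinus node recovery time, Wenckebach and 2:1 and
    retrograde conduction cycle lengths, effective refractory periods,
    arrhythmia inducibility and burden), and a normality-gated group
    statistics layer. A synthetic autonomic-tone RR/ECG generator and a
    virtual-heart stimulation simulator provide ground truth so every stage
    is testable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
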
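Package: raredx
Title: Symptom-Based Differential Diagnosis of Rare Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Ranks rare diseases against a patient's symptom set using a
    normalized set-difference score over a disease-symptom knowledge base,
    and evaluates the resulting differential diagnosis. Provides Monte
    Carlo estimation of score significance under random symptom queries,
    noise-injection benchmarks of diagnostic precision, sensitivity and
    F1, a seeded generator of synthetic disease-symptom knowledge bases,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
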
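Package: allofit
Title: Operational Model of Allosterism for GPCR Modulator Interaction Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying positive allosteric modulator (PAM)
    pharmacology from intracellular calcium mobilisation interaction
    experiments at the calcium-sensing receptor and similar GPCRs. Implements
    the operational model of cooperative agonism and allosteric modulation
    with an ambient-agonist correction, global nonlinear estimation of
    allosteric affinity (pKB), cooperativity (log alpha*beta) and intrinsic
    efficacy (log tauB) with identifiability diagnostics, a shared-slope
    four-parameter sigmoid fallback for ambiguous interactions, synthetic
    interaction-dataset generation for design and power work, and panel-level
    statistics (one-way ANOVA with Dunnett many-to-one comparisons and
    ago-PAM / pure-PAM profile classification).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    multcomp,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
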
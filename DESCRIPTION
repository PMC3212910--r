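Package: tissehr
Title: Two-Level Archetype Architecture for Healthcare Authorization and Claim Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A dual-model (reference model plus archetype) implementation of the
    Brazilian TISS healthcare authorization and claim standard. Provides a minimal
    openEHR-style reference-model kernel and an extended reference model with
    submission, claim, authorization and annex entry types and a claim lifecycle
    state machine; a parser and printer for the archetype definition language (ADL)
    dialect used by the TISS archetypes; an archetype constraint validator with slot
    resolution; a template engine that composes archetypes into the eleven TISS
    forms and flattens them to operational templates; programmatic builders for the
    three archetype fixture sets; a seedable synthetic claim generator with a
    single-violation mutant generator; and a simulated provider-payer extract
    exchange with REST-style resource semantics and payer adjudication. Claim
    documents serialize to canonical XML and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
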
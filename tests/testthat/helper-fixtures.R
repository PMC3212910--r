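# Shared, lazily built fixtures: the approach-1 repository, the template set
# and flattened operational templates are expensive enough to build once.
.tiss_cache <- new.env(parent = emptyenv())

test_repo <- function(approach = 1L) {
  key <- paste0("repo", approach)
  if (is.null(.tiss_cache[[key]])) .tiss_cache[[key]] <- tiss_repository(approach)
  .tiss_cache[[key]]
}

test_templates <- function() {
  if (is.null(.tiss_cache$templates)) .tiss_cache$templates <- tiss_templates()
  .tiss_cache$templates
}

test_opt <- function(name) {
  key <- paste0("opt::", name)
  if (is.null(.tiss_cache[[key]])) {
    .tiss_cache[[key]] <- flatten(test_templates()[[name]], test_repo())
  }
  .tiss_cache[[key]]
}

sample_claim <- function(seed = 1, template = "individual claim", ...) {
  generate_composition(generator_config(seed, template, ...),
                       test_repo(), test_templates())
}

reference_listing <- function(which = c("admin_entry", "extended")) {
  which <- match.arg(which)
  path <- system.file("extdata", "adl",
                      paste0("institutional_claim_", which, ".adl"),
                      package = "tissehr")
  paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
}

# Minimal hand-built admin entry conforming to the plain-RM institutional
# claim archetype, used where a deterministic small instance is clearer than
# a generated one.
tiny_institutional_entry <- function(extra_items = list()) {
  items <- c(list(
    element("submission ID", "at0002", dv_text("S-000123")),
    element("submission Date", "at0004", dv_text("2011-10-05")),
    element("date of encounter", "at0006", dv_date_time("2011-10-04T10:00:00")),
    element("billing date", "at0008", dv_text("2011-10-07")),
    element("status", "at0009", dv_text("submitted"))
  ), extra_items)
  admin_entry(
    "claim header", "at0000", "openEHR-EHR-ADMIN_ENTRY.institutional_claim.v1",
    subject = party_identified("Maria Souza", list(
      dv_identifier("PAT-000001", "health plan", "patient number"))),
    data = item_tree("components", "at0001", items),
    provider = party_identified("Dr. Ana Silva", list(
      dv_identifier("CRM-12345", "professional council", "professional id"))),
    other_participations = list(
      participation(party_identified("Hospital Santa Clara", list(
        dv_identifier("PRV-0001", "national provider registry", "provider id"))),
        "submitter"),
      participation(party_identified("Vida Plena Health Plan", list(
        dv_identifier("PAY-001", "supplementary health registry", "payer id"))),
        "payer"))
  )
}

tiny_composition <- function(entry = tiny_institutional_entry()) {
  composition("admission claim", "at0000", "openEHR-EHR-COMPOSITION.tiss_claim.v1",
              composer = party_identified("Dr. Ana Silva", list(
                dv_identifier("CRM-12345", "professional council", "professional id"))),
              context_start_time = "2011-10-05T09:00:00",
              content = list(entry), template = "admission claim")
}
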
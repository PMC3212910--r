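test_that("template configs round-trip through disk and load with validation", {
  tpl <- test_templates()[["admission claim"]]
  path <- withr::local_tempfile(fileext = ".tpl.json")
  write_template(tpl, path)
  back <- load_template(path, test_repo())
  expect_identical(back$name, tpl$name)
  expect_identical(back$root_archetype, tpl$root_archetype)
  expect_identical(back$slot_fills, tpl$slot_fills)
  expect_identical(back$exclusions, tpl$exclusions)
})

test_that("template validation lists every offender, not just the first", {
  tpl <- test_templates()[["consultation claim"]]
  tpl$slot_fills[["/content[at0001]"]] <- c(tpl$slot_fills[["/content[at0001]"]],
                                            "openEHR-EHR-CLUSTER.missing_concept.v1")
  tpl$exclusions <- c(tpl$exclusions, "/content[bad.path.v1]/data[at0001]/items[at0099]")
  errs <- validate_template(tpl, test_repo())
  expect_gte(length(errs), 2)
  expect_true(any(grepl("missing_concept", errs)))
  expect_true(any(grepl("does not resolve", errs)))
})

test_that("excluding a mandatory path and widening an interval are errors", {
  tpl <- test_templates()[["admission claim"]]
  inst <- "openEHR-EHR-ADMIN_ENTRY.institutional_claim.v1"
  # the data tree is mandatory ({1..1})
  tpl$exclusions <- sprintf("/content[%s]/data[at0001]", inst)
  errs <- validate_template(tpl, test_repo())
  expect_true(any(grepl("mandatory", errs)))

  tpl2 <- test_templates()[["admission claim"]]
  tpl2$occurrence_overrides <- stats::setNames(
    list(tissehr::adl_interval(0, Inf)),
    sprintf("/content[%s]/data[at0001]/items[at0004]", inst))
  errs2 <- validate_template(tpl2, test_repo())
  expect_true(any(grepl("widens", errs2)))
})

test_that("flattening substitutes slots, keeps provenance total and is idempotent", {
  opt <- test_opt("admission claim")
  labels <- vapply(form_schema(opt)$label, identity, character(1))
  # both clusters were pulled under the institutional claim entry
  expect_true("type of admission" %in% labels)
  expect_true("total costs" %in% labels)
  # provenance covers the filler roots with their source archetypes
  inst_path <- "/content[openEHR-EHR-ADMIN_ENTRY.institutional_claim.v1]"
  expect_identical(opt$provenance[[inst_path]]$archetype,
                   "openEHR-EHR-ADMIN_ENTRY.institutional_claim.v1")
  adm_path <- paste0(inst_path, "/data[at0001]/items[openEHR-EHR-CLUSTER.admission.v1]")
  expect_identical(opt$provenance[[adm_path]]$archetype, "openEHR-EHR-CLUSTER.admission.v1")
  # expanding a slot-free flattened tree changes nothing (idempotence)
  no_slot_def <- test_repo()$defs[["openEHR-EHR-CLUSTER.admission.v1"]]
  tpl0 <- template_definition("bare", "openEHR-EHR-CLUSTER.admission.v1")
  repo0 <- archetype_repository(list(no_slot_def))
  once <- flatten(tpl0, repo0)
  twice <- flatten(template_definition("bare", "openEHR-EHR-CLUSTER.admission.v1"), repo0)
  expect_identical(once$root, twice$root)
  expect_identical(once$root, no_slot_def$root)
})

test_that("a circular slot fill is rejected naming the cycle", {
  a <- archetype_definition("openEHR-EHR-CLUSTER.loop_a.v1",
    tissehr:::c_object("CLUSTER", "at0000", label = "a", attributes = list(
      tissehr:::c_attribute("items", children = list(
        tissehr:::c_slot("CLUSTER", "at0001", includes = "openEHR-EHR-CLUSTER.loop_b.v1"))))))
  b <- archetype_definition("openEHR-EHR-CLUSTER.loop_b.v1",
    tissehr:::c_object("CLUSTER", "at0000", label = "b", attributes = list(
      tissehr:::c_attribute("items", children = list(
        tissehr:::c_slot("CLUSTER", "at0001", includes = "openEHR-EHR-CLUSTER.loop_a.v1"))))))
  repo <- archetype_repository(list(a, b))
  tpl <- template_definition("loop", "openEHR-EHR-CLUSTER.loop_a.v1",
    slot_fills = list(
      "/items[at0001]" = "openEHR-EHR-CLUSTER.loop_b.v1",
      "/items[openEHR-EHR-CLUSTER.loop_b.v1]/items[at0001]" = "openEHR-EHR-CLUSTER.loop_a.v1"))
  err <- tryCatch(flatten(tpl, repo), error = identity)
  expect_s3_class(err, "tiss_template_error")
  expect_match(conditionMessage(err), "circular")
  expect_match(conditionMessage(err), "loop_a")
})

test_that("excluding the obstetrics cluster drops exactly its leaf fields", {
  pev <- "openEHR-EHR-EVALUATION.patient_evaluation.v1"
  with_tpl <- template_definition(
    "eval with obstetrics", "openEHR-EHR-COMPOSITION.tiss_claim.v1",
    slot_fills = list("/content[at0001]" = pev))
  without_tpl <- template_definition(
    "eval without obstetrics", "openEHR-EHR-COMPOSITION.tiss_claim.v1",
    slot_fills = list("/content[at0001]" = pev),
    exclusions = sprintf("/content[%s]/data[at0001]/items[at0010]", pev))
  n_with <- nrow(form_schema(flatten(with_tpl, test_repo())))
  n_without <- nrow(form_schema(flatten(without_tpl, test_repo())))
  # manual enumeration of the obstetrics cluster: 10 elements plus the
  # 5-count breakdown of the number of living births
  expect_identical(n_with - n_without, 15L)
})

test_that("template validation flags excluded elements and foreign codes", {
  comp <- sample_claim(21, "consultation claim")
  opt <- test_opt("consultation claim")
  expect_true(validate_against_template(comp, opt, test_repo())$valid)

  # smuggle an excluded element (cause of death, at0008) back into the form
  pev_i <- which(vapply(comp$content, function(e) {
    identical(e$archetype_id, "openEHR-EHR-EVALUATION.patient_evaluation.v1")
  }, logical(1)))
  bad <- comp
  bad$content[[pev_i]]$data$items <- c(
    bad$content[[pev_i]]$data$items,
    list(element("cause of death", "at0008", dv_text("natural"))))
  rep <- validate_against_template(bad, opt, test_repo())
  expect_false(rep$valid)
  f <- Filter(function(f) grepl("at0008", f$path), rep$findings)
  expect_length(f, 1)
  expect_identical(f[[1]]$rule, "OCCURRENCES_EXCEEDED")

  # a coded value outside the binding is reported
  prof_i <- which(vapply(comp$content, function(e) {
    identical(e$archetype_id, "openEHR-EHR-ADMIN_ENTRY.professional_claim.v1")
  }, logical(1)))
  bad2 <- comp
  items <- bad2$content[[prof_i]]$data$items
  for (k in seq_along(items)) {
    if (identical(items[[k]]$name, "type of encounter")) {
      items[[k]]$value <- dv_coded_text("99", "local")
    }
  }
  bad2$content[[prof_i]]$data$items <- items
  rep2 <- validate_against_template(bad2, opt, test_repo())
  rules <- vapply(rep2$findings, `[[`, character(1), "rule")
  expect_true("CODE_BINDING_VIOLATION" %in% rules)
})

test_that("form schemas are ordered, typed and deterministic", {
  opt <- test_opt("consultation claim")
  schema <- form_schema(opt)
  expect_true(all(c("label", "path", "kind", "required", "codes") %in% names(schema)))
  # the consultation form carries the encounter-type field of the admin archetype
  expect_true("type of encounter" %in% schema$label)
  expect_true(any(nzchar(schema$codes[schema$label == "type of encounter"])))
  # excluded elements are not form fields
  expect_false("cause of death" %in% schema$label)
  # every TISS element is optional, so nothing is required
  expect_false(any(schema$required))
  expect_identical(form_schema(test_opt("consultation claim")), schema)
})
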
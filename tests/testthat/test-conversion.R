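full_institutional_entry <- function() {
  layout <- tissehr:::admin_layouts()$institutional_claim
  items <- lapply(seq_along(layout), function(i) {
    lab <- unname(layout[[i]])
    value <- switch(lab,
      "submission ID" = dv_text("S-000123"),
      "original submission" = dv_text("S-000001"),
      "submission Date" = dv_text("2011-10-05"),
      "date of encounter" = dv_date_time("2011-10-04T10:00:00"),
      "billing date" = dv_text("2011-10-07"),
      "status" = dv_text("submitted"),
      dv_text(paste("value of", lab)))
    element(lab, names(layout)[[i]], value)
  })
  e <- tiny_institutional_entry()
  e$data$items <- items
  e
}

test_that("an institutional claim entry converts to the extended model", {
  # all 11 elements populated: 4 become reference-model attributes, the
  # status element becomes the composition's ISM transition, 6 remain
  comp <- tiny_composition(full_institutional_entry())
  ext <- convert_base_to_extended(comp)
  entry <- ext$content[[1]]
  expect_s3_class(entry, "tiss_institutional_claim")
  expect_identical(entry$submission_id, "S-000123")
  expect_identical(entry$original_submission, "S-000001")
  expect_identical(entry$submission_date, "2011-10-05")
  expect_identical(entry$billing_date, "2011-10-07")
  expect_length(entry$data$items, 6)
  expect_identical(ext$ism_transition$current_state, "SUBMITTED")
  # submitter is the provider organization, submittee the payer
  expect_identical(entry$submitter$name, "Hospital Santa Clara")
  expect_identical(entry$submittee$name, "Vida Plena Health Plan")
})

test_that("authorization conversion sets authorization_id, validity and is_response", {
  comp <- sample_claim(3, "admission authorization")
  ext <- convert_base_to_extended(comp)
  entry <- ext$content[[1]]
  expect_identical(entry$rm_type, "AUTHORIZATION")
  expect_true(entry$is_response)
  expect_match(entry$authorization_id, "^A-")
  expect_false(is.null(entry$validity_start))
  expect_true(entry$validity_start <= entry$validity_end)
  # authorization requests carry no authorization number: not a response
  req <- convert_base_to_extended(sample_claim(3, "admission request"))
  expect_false(req$content[[1]]$is_response)
})

test_that("a missing status element leaves the ISM transition absent", {
  e <- tiny_institutional_entry()
  e$data$items <- Filter(function(it) !identical(it$name, "status"), e$data$items)
  ext <- convert_base_to_extended(tiny_composition(e))
  expect_null(ext$ism_transition)
  expect_identical(ext$content[[1]]$submission_id, "S-000123")
})

test_that("conversion errors name every missing mandatory field", {
  e <- tiny_institutional_entry()
  e$data$items <- Filter(function(it) !identical(it$name, "submission ID"), e$data$items)
  e$other_participations <- e$other_participations[2] # drop the submitter
  err <- tryCatch(convert_base_to_extended(tiny_composition(e)), error = identity)
  expect_s3_class(err, "tiss_conversion_error")
  expect_match(conditionMessage(err), "submission ID")
  expect_match(conditionMessage(err), "submitter")
  # unknown source archetype
  comp <- tiny_composition()
  comp$content[[1]]$archetype_id <- "openEHR-EHR-ADMIN_ENTRY.someting_else.v1"
  expect_error(convert_base_to_extended(comp), class = "tiss_conversion_error")
})

test_that("extended-to-base restores the performer and participants mappings", {
  prof <- convert_base_to_extended(sample_claim(5, "individual claim"))
  entry <- prof$content[[tissehr:::find_claim_entry(prof, extended = TRUE)]]
  expect_s3_class(entry, "tiss_professional_claim")
  back <- convert_extended_to_base(prof)
  bentry <- back$content[[tissehr:::find_claim_entry(back, extended = FALSE)]]
  # the admin entry's provider attribute holds the performer
  expect_identical(bentry$provider$name, entry$performer$name)

  inst <- convert_base_to_extended(sample_claim(5, "admission claim"))
  ientry <- inst$content[[tissehr:::find_claim_entry(inst, extended = TRUE)]]
  expect_s3_class(ientry, "tiss_institutional_claim")
  expect_gte(length(ientry$participants), 1)
  iback <- convert_extended_to_base(inst)
  ibentry <- iback$content[[tissehr:::find_claim_entry(iback, extended = FALSE)]]
  professionals <- Filter(function(p) identical(p[["function"]], "professional"),
                          ibentry$other_participations)
  expect_length(professionals, length(ientry$participants))
})

test_that("the base/extended round trip is the identity and conserves values", {
  claim_templates <- c("individual claim", "consultation claim", "admission request",
                       "admission authorization", "admission claim",
                       "tests and procedures claim", "other charges")
  for (tpl in claim_templates) {
    for (seed in 1:3) {
      comp <- sample_claim(seed, tpl)
      ext <- convert_base_to_extended(comp)
      expect_true(structural_equals(comp, convert_extended_to_base(ext)),
                  label = sprintf("round trip identity for %s seed %d", tpl, seed))
      expect_identical(claim_value_multiset(comp), claim_value_multiset(ext),
                       label = sprintf("value conservation for %s seed %d", tpl, seed))
    }
  }
})
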
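test_that("package_extract groups compositions by subject", {
  ids <- id_source()
  provider <- party_identified("Hospital Santa Clara", list(
    dv_identifier("PRV-0001", "national provider registry", "provider id")))
  payer <- party_identified("Vida Plena Health Plan", list(
    dv_identifier("PAY-001", "supplementary health registry", "payer id")))
  same1 <- tiny_composition()
  same2 <- tiny_composition()
  ext <- package_extract(list(same1, same2), provider, payer, ids)
  expect_length(ext$items, 1)
  expect_length(ext$items[[1]]$compositions, 2)

  other <- tiny_composition()
  other$content[[1]]$subject <- party_identified("Jose Costa", list(
    dv_identifier("PAT-000002", "health plan", "patient number")))
  ext2 <- package_extract(list(same1, other), provider, payer, ids)
  expect_length(ext2$items, 2)
  expect_error(package_extract(list(), provider, payer, ids), class = "tiss_value_error")

  # serialization round trips, in both formats and across them
  for (e in list(ext, ext2)) {
    expect_true(structural_equals(e, from_tiss_json(to_tiss_json(e))))
    expect_true(structural_equals(e, from_tiss_xml(to_tiss_xml(e))))
    expect_true(structural_equals(from_tiss_xml(to_tiss_xml(e)),
                                  from_tiss_json(to_tiss_json(from_tiss_xml(to_tiss_xml(e))))))
  }
})

test_that("the transport verbs implement REST resource semantics", {
  store <- resource_store()
  register_org(store, "PAY-001")
  expect_error(transport_get(store, "UNKNOWN", "r0001"), class = "tiss_value_error")

  posted <- transport_post(store, "PAY-001", "payload-1")
  expect_identical(posted$status, 201L)
  got <- transport_get(store, "PAY-001", posted$resource_id)
  expect_identical(got$payload, "payload-1")

  # PUT is idempotent: one stored copy, every operation logged
  transport_put(store, "PAY-001", "fixed-id", "payload-2")
  transport_put(store, "PAY-001", "fixed-id", "payload-2")
  expect_identical(transport_get(store, "PAY-001", "fixed-id")$payload, "payload-2")
  puts <- Filter(function(e) e$verb == "PUT", store$log)
  expect_length(puts, 2)

  expect_identical(transport_delete(store, "PAY-001", "fixed-id")$status, 204L)
  expect_identical(transport_get(store, "PAY-001", "fixed-id")$status, 404L)
  expect_identical(transport_delete(store, "PAY-001", "fixed-id")$status, 404L)
})

test_that("adjudication grants authorizations with validity and advances lifecycles", {
  sc <- generate_scenario(41, n_requests = 2)
  ext <- sc$steps[[1]]$extract
  resp <- adjudicate(ext, policy_approve_all(validity_days = 30),
                     test_repo(), test_templates())
  comps <- unlist(lapply(resp$items, `[[`, "compositions"), recursive = FALSE)
  n_req <- sum(vapply(ext$items, function(it) length(it$compositions), integer(1)))
  expect_length(comps, n_req) # one response per request
  for (r in comps) {
    entry <- r$content[[1]]
    expect_identical(entry$rm_type, "AUTHORIZATION")
    expect_true(entry$is_response)
    expect_match(entry$authorization_id, "^AUTH-")
    expect_identical(as.integer(as.Date(entry$validity_end) - as.Date(entry$validity_start)), 30L)
    expect_match(entry$original_submission, "^S-")
    expect_true(validate_history(r$lifecycle)$valid)
    expect_identical(r$ism_transition$current_state, "COMPLETED")
  }
  # source and target organizations are swapped on the response
  expect_identical(resp$source_org$name, ext$target_org$name)
  expect_identical(resp$target_org$name, ext$source_org$name)

  denied <- adjudicate(ext, policy_deny_all(), test_repo(), test_templates())
  for (r in unlist(lapply(denied$items, `[[`, "compositions"), recursive = FALSE)) {
    expect_identical(r$ism_transition$current_state, "DENIED")
    expect_null(r$content[[1]]$authorization_id)
    expect_true(validate_history(r$lifecycle)$valid)
  }
})

test_that("structurally invalid claims come back for correction with an annex", {
  sc <- generate_scenario(43, n_requests = 1)
  ext <- sc$steps[[1]]$extract
  comp <- ext$items[[1]]$compositions[[1]]
  mut <- mutate_for_violation(comp, "NODE_ID_UNKNOWN",
                              test_opt("admission request"), test_repo())
  ext$items[[1]]$compositions[[1]] <- mut$composition
  resp <- adjudicate(ext, policy_approve_all(), test_repo(), test_templates())
  r <- resp$items[[1]]$compositions[[1]]
  expect_identical(r$ism_transition$current_state, "RETURNED_FOR_CORRECTION")
  entry <- r$content[[1]]
  expect_identical(entry$rm_type, "ANNEX")
  expect_match(entry$complements, "^S-")
  texts <- vapply(entry$data$items, function(it) it$value$value, character(1))
  expect_true(any(grepl("NODE_ID_UNKNOWN", texts)))
})

test_that("the full round trip is reproducible and terminates every history", {
  run <- function() {
    run_roundtrip(generate_scenario(47, n_requests = 2, n_claims = 1),
                  policy_approve_all(), test_repo(), test_templates())
  }
  log1 <- run()
  log2 <- run()
  expect_identical(exchange_log_json(log1), exchange_log_json(log2))
  expect_gt(length(log1$entries), 0)
  expect_length(log1$responses, 3)
  for (r in log1$responses) {
    expect_true(validate_history(r$lifecycle)$valid)
    expect_identical(r$ism_transition$current_state, "COMPLETED")
  }
  # the store saw the provider-side POST and the payer-side response
  verbs <- vapply(log1$store$log, `[[`, character(1), "verb")
  expect_true(all(c("POST", "GET") %in% verbs))
})

test_that("a denied submission can be resubmitted and completed", {
  log <- run_roundtrip(generate_scenario(53, n_requests = 2),
                       policy_deny_then_approve(), test_repo(), test_templates(),
                       resubmit = TRUE)
  expect_length(log$responses, 2)
  for (r in log$responses) {
    states <- vapply(r$lifecycle, `[[`, character(1), "current_state")
    expect_identical(states, c("SUBMITTED", "DENIED", "SUBMITTED", "COMPLETED"))
    expect_true(validate_history(r$lifecycle)$valid)
  }
})
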
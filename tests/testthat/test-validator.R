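inst_archetype <- function() {
  test_repo()$defs[["openEHR-EHR-ADMIN_ENTRY.institutional_claim.v1"]]
}

test_that("an instance with all optional elements absent is valid", {
  e <- tiny_institutional_entry()
  e$data$items <- list()
  rep <- validate_instance(e, inst_archetype(), test_repo())
  expect_true(rep$valid)
  expect_length(rep$findings, 0)
})

test_that("a duplicated {0..1} element yields exactly one occurrences finding at its path", {
  e <- tiny_institutional_entry(list(element("submission Date", "at0004",
                                             dv_text("2011-10-06"))))
  rep <- validate_instance(e, inst_archetype(), test_repo())
  expect_false(rep$valid)
  hits <- Filter(function(f) f$rule == "OCCURRENCES_EXCEEDED", rep$findings)
  expect_length(hits, 1)
  expect_identical(hits[[1]]$path, "/data[at0001]/items[at0004]")
  # the repeatable submission ID element may occur many times
  e2 <- tiny_institutional_entry(list(element("submission ID", "at0002", dv_text("S-2"))))
  expect_true(validate_instance(e2, inst_archetype(), test_repo())$valid)
})

test_that("slot include lists are enforced, with alias-aware filler validation", {
  mk_filler <- function(id, label, item_label, item_id) {
    cluster(label, "at0000", list(element(item_label, item_id, dv_text("x"))),
            archetype_id = id)
  }
  ok <- tiny_institutional_entry(list(
    mk_filler("openEHR-EHR-CLUSTER.admission.v1", "admission", "type of admission", "at0001")))
  expect_true(validate_instance(ok, inst_archetype(), test_repo())$valid)
  # the printed include list names costs.v1; total_costs fills via the alias
  ok2 <- tiny_institutional_entry(list(
    cluster("total costs", "at0000",
            list(element("total costs", "at0001", dv_money(120.5))),
            archetype_id = "openEHR-EHR-CLUSTER.total_costs.v1")))
  rep2 <- validate_instance(ok2, inst_archetype(), test_repo())
  expect_true(rep2$valid)
  # a care archetype is not included by the cluster slot
  bad <- tiny_institutional_entry(list(
    mk_filler("openEHR-EHR-CLUSTER.odontologic_evaluation.v1", "odontologic evaluation",
              "periodontal disease", "at0002")))
  rep <- validate_instance(bad, inst_archetype(), test_repo())
  rules <- vapply(rep$findings, `[[`, character(1), "rule")
  expect_true("SLOT_INCLUDE_VIOLATION" %in% rules)
  # included but missing from the repository: a finding, not an exception
  gap_repo <- archetype_repository(Filter(
    function(d) format(d$id) != "openEHR-EHR-CLUSTER.admission.v1",
    unname(tissehr::fixture_archetypes(1))))
  rep3 <- validate_instance(ok, inst_archetype(), gap_repo)
  rules3 <- vapply(rep3$findings, `[[`, character(1), "rule")
  expect_true("SLOT_FILLER_INVALID" %in% rules3)
  # filler subtrees are validated against their own archetypes
  deep_bad <- tiny_institutional_entry(list(
    mk_filler("openEHR-EHR-CLUSTER.admission.v1", "admission", "bogus", "at9999")))
  repd <- validate_instance(deep_bad, inst_archetype(), test_repo())
  expect_false(repd$valid)
  f <- repd$findings[[1]]
  expect_identical(f$rule, "NODE_ID_UNKNOWN")
  expect_match(f$path, "^/data\\[at0001\\]/items\\[openEHR-EHR-CLUSTER.admission.v1\\]")
})

test_that("value constraints accept the right variants", {
  dt_cons <- tissehr:::c_primitive("DV_DATE_TIME")
  txt_cons <- tissehr:::c_primitive("DV_TEXT")
  expect_null(check_value_constraint(dv_text("anything"), txt_cons))
  expect_null(check_value_constraint(dv_coded_text("01", "local"), txt_cons))
  expect_null(check_value_constraint(dv_date_time("2011-10-12T00:00:00"), dt_cons))
  f <- check_value_constraint(dv_text("2011"), dt_cons)
  expect_identical(f$rule, "VALUE_TYPE_MISMATCH")
  # a text value in the date-of-encounter element is reported in context
  e <- tiny_institutional_entry()
  e$data$items[[3]]$value <- dv_text("October 4th")
  rep <- validate_instance(e, inst_archetype(), test_repo())
  expect_false(rep$valid)
  expect_identical(rep$findings[[1]]$path, "/data[at0001]/items[at0006]/value")
})

test_that("findings are canonically ordered and runs are byte-identical", {
  e <- tiny_institutional_entry(list(
    element("bogus", "at9999", dv_text("x")),
    element("submission Date", "at0004", dv_text("2011-10-06"))))
  e$data$items[[3]]$value <- dv_text("not a date")
  r1 <- validate_instance(e, inst_archetype(), test_repo())
  r2 <- validate_instance(e, inst_archetype(), test_repo())
  expect_identical(as.character(report_to_json(r1)), as.character(report_to_json(r2)))
  paths <- vapply(r1$findings, `[[`, character(1), "path")
  expect_identical(paths, sort(paths, method = "radix"))
})

test_that("removing an optional subtree never introduces an error", {
  comp <- sample_claim(9, "admission claim")
  opt <- test_opt("admission claim")
  expect_true(validate_against_template(comp, opt, test_repo())$valid)
  entry_i <- tissehr:::find_claim_entry(comp, extended = FALSE)
  pruned <- comp
  # drop each optional top-level item of the claim entry in turn
  items <- pruned$content[[entry_i]]$data$items
  for (k in seq_along(items)) {
    variant <- comp
    variant$content[[entry_i]]$data$items <- items[-k]
    expect_true(validate_against_template(variant, opt, test_repo())$valid,
                label = sprintf("pruning item %d keeps the claim valid", k))
  }
})
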
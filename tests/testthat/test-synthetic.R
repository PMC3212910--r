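test_that("generation is deterministic and template-valid", {
  a <- sample_claim(5, "dental claim")
  b <- sample_claim(5, "dental claim")
  expect_true(structural_equals(a, b))
  expect_identical(to_tiss_json(a), to_tiss_json(b))
  c <- sample_claim(6, "dental claim")
  expect_false(structural_equals(a, c))

  for (tpl in tiss_form_names()) {
    for (i in 1:3) {
      comp <- sample_claim(11, tpl, index = i)
      rep <- validate_against_template(comp, test_opt(tpl), test_repo())
      expect_true(rep$valid, label = sprintf("%s #%d valid", tpl, i))
    }
  }
  expect_error(sample_claim(1, "no such form"), class = "tiss_value_error")
})

test_that("generated parties are identified and admissions are coherent", {
  found_admission <- FALSE
  for (i in 1:10) {
    comp <- sample_claim(17, "admission claim", index = i)
    for (e in comp$content) {
      expect_s3_class(e$subject, "tiss_party_identified")
      expect_gte(length(e$subject$identifiers), 1)
    }
    adm <- resolve_path(comp, paste0(
      "/content[openEHR-EHR-ADMIN_ENTRY.institutional_claim.v1]",
      "/data[at0001]/items[openEHR-EHR-CLUSTER.admission.v1]"))
    if (length(adm)) {
      vals <- function(lab) {
        Filter(function(it) identical(it$name, lab), adm[[1]]$items)
      }
      req <- vals("requested number of days")
      auth <- vals("authorized number of days")
      if (length(req) && length(auth)) {
        found_admission <- TRUE
        expect_lte(req[[1]]$value$value, auth[[1]]$value$value)
      }
      di <- vals("date of admission")
      dd <- vals("discharge date")
      if (length(di) && length(dd)) {
        expect_true(di[[1]]$value$value <= dd[[1]]$value$value)
      }
    }
  }
  expect_true(found_admission)
})

test_that("costs are non-negative and bound elements use bound codes", {
  comp <- sample_claim(23, "individual claim", fill = "all")
  money <- list()
  walk <- function(x) {
    if (inherits(x, "tiss_dv_money")) money[[length(money) + 1L]] <<- x
    if (is.list(x)) for (el in x) if (is.list(el)) walk(el)
  }
  walk(unclass(comp))
  expect_gt(length(money), 0)
  for (m in money) expect_gte(m$amount, 0)
  toc <- resolve_path(comp, paste0(
    "/content[openEHR-EHR-ADMIN_ENTRY.professional_claim.v1]/data[at0001]/items[at0007]"))
  expect_length(toc, 1)
  expect_s3_class(toc[[1]]$value, "tiss_dv_coded_text")
  expect_true(toc[[1]]$value$code %in% c("01", "02", "03"))
})

test_that("mutants trigger exactly their declared rule at the declared path", {
  rules <- setdiff(mutation_rules(), "SLOT_FILLER_INVALID")
  checked <- character()
  for (tpl in c("admission claim", "individual claim", "consultation claim")) {
    comp <- sample_claim(31, tpl, fill = "all")
    opt <- test_opt(tpl)
    expect_true(validate_against_template(comp, opt, test_repo())$valid)
    for (rule in rules) {
      mut <- mutate_for_violation(comp, rule, opt, test_repo())
      if (is_mutation_skip(mut)) next
      checked <- union(checked, rule)
      rep <- validate_against_template(mut$composition, opt, test_repo())
      expect_false(rep$valid, label = sprintf("%s mutant invalid (%s)", rule, tpl))
      hit <- Filter(function(f) {
        identical(f$rule, mut$expected$rule) && identical(f$path, mut$expected$path)
      }, rep$findings)
      expect_gte(length(hit), 1)
      # the unmutated composition is still valid: nothing was modified in place
      expect_true(validate_against_template(comp, opt, test_repo())$valid)
    }
  }
  expect_setequal(checked, rules)
  # the filler-gap rule needs a repository gap, not an instance mutation
  skip_sig <- mutate_for_violation(sample_claim(31, "admission claim"),
                                   "SLOT_FILLER_INVALID",
                                   test_opt("admission claim"), test_repo())
  expect_true(is_mutation_skip(skip_sig))
  expect_error(mutate_for_violation(sample_claim(31, "admission claim"), "NO_SUCH_RULE",
                                    test_opt("admission claim"), test_repo()),
               class = "tiss_value_error")
})
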
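test_that("each approach builds ten archetypes that all re-parse", {
  for (approach in 1:3) {
    outdir <- withr::local_tempdir()
    paths <- build_fixtures(approach, outdir)
    expect_length(paths, 10)
    expect_true(file.exists(file.path(outdir, "manifest.json")))
    for (p in paths) {
      def <- read_archetype(p)
      rt <- parse_archetype(serialize_archetype(def))
      expect_identical(def$root, rt$root)
    }
  }
  # rebuilding is byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  build_fixtures(1, d1)
  build_fixtures(1, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("approach-3 roots are the extended claim classes", {
  defs <- fixture_archetypes(3)
  expect_identical(defs$professional_claim$root$rm_type, "PROFESSIONAL_CLAIM")
  expect_identical(defs$institutional_claim$root$rm_type, "INSTITUTIONAL_CLAIM")
  expect_identical(defs$authorization$root$rm_type, "AUTHORIZATION")
  expect_identical(defs$authorization_request$root$rm_type, "AUTHORIZATION")
  expect_identical(format(defs$professional_claim$id),
                   "openEHR-EHR-PROFESSIONAL_CLAIM.professional_claim.v1")
  # approach 2 roots the clinical content in CLUSTER
  defs2 <- fixture_archetypes(2)
  expect_identical(defs2$patient_evaluation$root$rm_type, "CLUSTER")
  expect_identical(defs2$claim_services$root$rm_type, "CLUSTER")
  # and its admin slot accepts every cluster archetype
  inv2 <- inventory(2)
  expect_length(inv2$entries$professional_claim$slot_includes, 5)
})

test_that("inventories match the archetype tables", {
  inv <- inventory(1)
  expect_length(inv$entries$patient_evaluation$elements, 8)
  expect_length(inv$entries$total_costs$elements, 10)
  expect_length(inv$entries$claim_services$elements, 13)
  expect_length(inv$entries$admission$elements, 9)
  expect_length(inv$entries$institutional_claim$elements, 11)
  expect_length(inv$entries$professional_claim$elements, 12)
  expect_identical(inv$entries$patient_evaluation$elements[1:4],
                   c("clinical indication", "type of disease",
                     "duration of disease", "accident indication"))
  expect_true("number of living births" %in% inv$entries$patient_evaluation$clusters)
  inv3 <- inventory(3)
  expect_identical(inv3$entries$authorization_request$elements,
                   c("type of encounter", "date of encounter", "comments"))
  expect_length(inv3$entries$institutional_claim$elements, 7)
})

test_that("extended-model inventories drop exactly the absorbed header elements", {
  inv1 <- inventory(1)
  inv3 <- inventory(3)
  for (concept in c("professional_claim", "institutional_claim",
                    "authorization", "authorization_request")) {
    e1 <- inv1$entries[[concept]]$elements
    e3 <- inv3$entries[[concept]]$elements
    expect_identical(setdiff(e1, e3), as.character(rm_absorbed_labels(concept)),
                     label = paste("absorbed set for", concept))
    expect_length(setdiff(e3, e1), 0)
  }
  # the clinical and cluster archetypes are unchanged between the approaches
  for (concept in c("patient_evaluation", "odontologic_evaluation",
                    "claim_services", "admission", "total_costs")) {
    expect_identical(inv1$entries[[concept]]$elements, inv3$entries[[concept]]$elements)
  }
})

test_that("every slot include resolves in the repository after aliasing", {
  for (approach in 1:3) {
    repo <- tiss_repository(approach)
    inv <- inventory(approach)
    for (e in inv$entries) {
      for (inc in e$slot_includes) {
        expect_false(is.null(repo_get(repo, inc)),
                     label = sprintf("%s include %s resolves", e$id, inc))
      }
    }
  }
})

test_that("built institutional claims token-match the bundled reference listings", {
  built1 <- serialize_archetype(fixture_archetypes(1)$institutional_claim)
  expect_length(adl_token_diff(reference_listing("admin_entry"), built1), 0)
  built3 <- serialize_archetype(fixture_archetypes(3)$institutional_claim)
  expect_length(adl_token_diff(reference_listing("extended"), built3), 0)
})

test_that("the template fixture set covers exactly the eleven TISS forms", {
  tpls <- test_templates()
  expect_identical(names(tpls), tiss_form_names())
  expect_length(tpls, 11)
  outdir <- withr::local_tempdir()
  paths <- build_templates(outdir)
  expect_length(paths, 11)
  for (p in paths) {
    tpl <- load_template(p, test_repo())
    expect_true(tpl$name %in% tiss_form_names())
  }
})
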
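test_that("archetype ids parse, normalize and render canonically", {
  id <- parse_archetype_id("openEHR-EHR-EVALUATION.patient_evaluation.v1")
  expect_identical(id$rm_entity, "EVALUATION")
  expect_identical(id$concept, "patient_evaluation")
  expect_identical(id$version, 1L)
  expect_false(attr(id, "normalized"))
  short <- parse_archetype_id("openEHR-CLUSTER.admission.v1")
  expect_true(attr(short, "normalized"))
  expect_identical(format(short), "openEHR-EHR-CLUSTER.admission.v1")
  expect_error(parse_archetype_id("nonsense"), class = "tiss_parse_error")
  expect_error(parse_archetype_id("openEHR-EHR-CLUSTER.admission"), class = "tiss_parse_error")
})

test_that("the bundled reference listings parse to the expected trees", {
  adm <- parse_archetype(reference_listing("admin_entry"))
  expect_identical(adm$root$rm_type, "ADMIN_ENTRY")
  tree <- adm$root$attributes[[1]]$children[[1]]
  expect_identical(tree$rm_type, "ITEM_TREE")
  expect_identical(tree$node_id, "at0001")
  expect_identical(tissehr:::count_elements(adm), 11L)
  kids <- tree$attributes[[1]]$children
  slots <- Filter(function(k) k$kind == "slot", kids)
  expect_length(slots, 1)
  expect_length(slots[[1]]$includes, 2)
  expect_identical(slots[[1]]$node_id, "at0015")
  # labels come from the trailing comments
  expect_identical(kids[[1]]$label, "submission ID")
  expect_identical(format(kids[[1]]$occurrences), "0..*")
  expect_identical(format(kids[[3]]$occurrences), "0..1")

  ext <- parse_archetype(reference_listing("extended"))
  expect_identical(ext$root$rm_type, "INSTITUTIONAL_CLAIM")
  expect_identical(tissehr:::count_elements(ext), 7L)
  ids <- tissehr:::constraint_node_ids(ext$root)
  expect_setequal(setdiff(ids, "at0000"),
                  c("at0001", sprintf("at%04d", 2:8), "at0010"))
})

test_that("any-constraints, parse errors and type registration behave", {
  anydef <- parse_archetype("ADMIN_ENTRY[at0000] matches {*}")
  expect_true(anydef$root$any)
  expect_length(anydef$root$attributes, 0)

  err <- tryCatch(parse_archetype("ADMIN_ENTRY[at0000] matches {\ndata matches {"),
                  error = identity)
  expect_s3_class(err, "tiss_parse_error")
  expect_match(conditionMessage(err), "unbalanced|end of input")

  err <- tryCatch(parse_archetype("ADMIN_ENTRY[atXYZ] matches {*}"), error = identity)
  expect_match(conditionMessage(err), "line 1")
  expect_match(conditionMessage(err), "node id")

  err <- tryCatch(
    parse_archetype("ELEMENT[at0001] occurrences matches {1..x} matches {*}"),
    error = identity)
  expect_s3_class(err, "tiss_parse_error")

  err <- tryCatch(parse_archetype("MYSTERY_TYPE[at0000] matches {*}"), error = identity)
  expect_match(conditionMessage(err), "MYSTERY_TYPE")

  dup <- "CLUSTER[at0000] matches { items matches { ELEMENT[at0001] matches {*} ELEMENT[at0001] matches {*} } }"
  err <- tryCatch(parse_archetype(dup), error = identity)
  expect_match(conditionMessage(err), "duplicate node id")
})

test_that("serialization is canonical and a parse fixed point", {
  # both reference listings reach a fixed point after one canonicalization
  for (which in c("admin_entry", "extended")) {
    d1 <- parse_archetype(reference_listing(which))
    s1 <- serialize_archetype(d1)
    d2 <- parse_archetype(s1)
    expect_identical(serialize_archetype(d2), s1)
    expect_identical(d1$root, d2$root)
    expect_length(adl_token_diff(reference_listing(which), s1), 0)
  }
  # interval printing
  expect_identical(format(adl_interval(0, Inf)), "0..*")
  expect_match(serialize_archetype(parse_archetype(reference_listing("admin_entry"))),
               "occurrences matches \\{0\\.\\.\\*\\}")
  # no ontology section when there are no term definitions
  bare <- archetype_definition(NULL, tissehr:::c_object("ADMIN_ENTRY", "at0000", any = TRUE))
  expect_false(grepl("ontology", serialize_archetype(bare)))
})

test_that("parse after print is the identity on random constraint trees", {
  for (seed in 1:60) {
    def <- random_archetype_def(seed)
    rt <- parse_archetype(serialize_archetype(def))
    expect_def_identical(def, rt)
  }
})

test_that("archetype files round-trip through disk", {
  def <- random_archetype_def(7)
  path <- withr::local_tempfile(fileext = ".adl")
  write_archetype(def, path)
  expect_def_identical(def, read_archetype(path))
})
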
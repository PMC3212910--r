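test_that("data values canonicalize at construction", {
  expect_equal(dv_money("1,200.00")$amount, 1200)
  expect_equal(dv_money("1,200.005")$amount, 1200.0, tolerance = 0.01)
  expect_identical(dv_date_time("2011-10-12 08:30")$value, "2011-10-12T08:30:00")
  expect_error(dv_date_time("yesterday"), class = "tiss_value_error")
  expect_error(dv_count(-1), class = "tiss_value_error")
  expect_error(dv_money(1, currency = "real"), class = "tiss_value_error")
  expect_error(dv_date("12/10/2011"), class = "tiss_value_error")
})

test_that("node construction enforces kernel invariants", {
  expect_error(element("x", "atXX"), class = "tiss_value_error")
  # at0000 is reserved for archetype roots
  expect_error(element("x", "at0000"), class = "tiss_value_error")
  e <- element("x", "at0000", archetype_id = "openEHR-EHR-CLUSTER.admission.v1")
  expect_identical(e$node_id, "at0000")
  expect_error(cluster("c", "at0001", list()), class = "tiss_type_error")
  expect_error(item_list("l", "at0001", list(cluster("c", "at0002", list(element("e", "at0003"))))),
               class = "tiss_type_error")
  rows_ok <- list(cluster("r", "at0002", list(element("a", "at0003"), element("b", "at0004"))),
                  cluster("r", "at0002", list(element("a", "at0003"), element("b", "at0004"))))
  expect_s3_class(item_table("t", "at0001", rows_ok), "tiss_item_table")
  rows_bad <- list(rows_ok[[1]],
                   cluster("r", "at0002", list(element("b", "at0004"), element("a", "at0003"))))
  expect_error(item_table("t", "at0001", rows_bad), class = "tiss_value_error")
})

test_that("paths parse, render and round-trip canonically", {
  cases <- c("", "/data[at0001]", "/data[at0001]/items[at0004]",
             "/content[openEHR-EHR-ADMIN_ENTRY.authorization.v1]/data[at0001]",
             "/items[at0002][1]")
  for (p in cases) {
    expect_identical(format(parse_instance_path(p)), p)
  }
  expect_error(parse_instance_path("data[at0001]"), class = "tiss_parse_error")
  expect_error(parse_instance_path("/data[at1]"), class = "tiss_parse_error")
  err <- tryCatch(parse_instance_path("/data[at0001]/??"), error = identity)
  expect_match(conditionMessage(err), "malformed path near")
})

test_that("resolve_path matches nodes by attribute, node id and index", {
  entry <- tiny_institutional_entry()
  # identity path
  expect_identical(resolve_path(entry, ""), list(entry))
  # the submission Date element lives at /data[at0001]/items[at0004]
  hit <- resolve_path(entry, "/data[at0001]/items[at0004]")
  expect_length(hit, 1)
  expect_identical(hit[[1]]$name, "submission Date")
  # unknown node id yields an empty result, not an error
  expect_length(resolve_path(entry, "/data[at0001]/items[at9999]"), 0)
  # node-id conflict never matches: every hit carries the queried id
  for (seg_id in c("at0002", "at0006", "at0009")) {
    hits <- resolve_path(entry, sprintf("/data[at0001]/items[%s]", seg_id))
    for (h in hits) expect_identical(h$node_id, seg_id)
  }
  # sibling index disambiguates duplicated node ids
  dup <- tiny_institutional_entry(list(element("comments", "at0012", dv_text("a")),
                                       element("comments", "at0012", dv_text("b"))))
  expect_identical(resolve_path(dup, "/data[at0001]/items[at0012][1]")[[1]]$value$value, "b")
  # archetype-id segments address slot fillers
  comp <- tiny_composition()
  ent <- resolve_path(comp, "/content[openEHR-EHR-ADMIN_ENTRY.institutional_claim.v1]")
  expect_length(ent, 1)
})

test_that("structural equality is canonical and an equivalence relation", {
  a <- element("cost", "at0009", dv_money("1,200.00"))
  b <- element("cost", "at0009", dv_money("1200.00"))
  expect_true(structural_equals(a, b))
  t1 <- element("when", "at0004", dv_date_time("2011-10-12 08:30"))
  t2 <- element("when", "at0004", dv_date_time("2011-10-12T08:30:00"))
  expect_true(structural_equals(t1, t2))
  # type mismatch: a tree and a list with identical elements differ
  els <- list(element("a", "at0002", dv_text("x")))
  expect_false(structural_equals(item_tree("s", "at0001", els),
                                 item_list("s", "at0001", els)))
  # reflexive / symmetric / transitive over generated compositions
  comps <- lapply(1:3, function(s) sample_claim(s, "consultation claim"))
  for (x in comps) expect_true(structural_equals(x, x))
  x2 <- sample_claim(1, "consultation claim")
  expect_true(structural_equals(comps[[1]], x2))
  expect_true(structural_equals(x2, comps[[1]]))
  expect_false(structural_equals(comps[[1]], comps[[2]]))
})

test_that("collect_links returns every link with its owner path in document order", {
  expect_length(collect_links(tiny_institutional_entry()), 0)
  l1 <- link_to("justified by", "CLAIM_ITEM_DIAGNOSIS", "comp-1/data[at0001]/items[at0006]")
  l2 <- link_to("justified by", "CLAIM_ITEM_DIAGNOSIS", "comp-1/data[at0001]/items[at0007]")
  svc <- action("claim services", "at0000", "openEHR-EHR-ACTION.claim_services.v1",
                subject = party_self(),
                data = item_tree("components", "at0001", list(
                  element("procedure", "at0003", dv_text("physical therapy"),
                          links = list(l1, l2)))))
  found <- collect_links(svc)
  expect_length(found, 2)
  expect_identical(found[[1]]$link$target, l1$target)
  expect_identical(found[[1]]$path, "/data[at0001]/items[at0003]")
  # brute-force full-tree scan oracle: links at nested cluster depth are found
  deep <- cluster("outer", "at0020", list(
    cluster("inner", "at0021", list(
      element("leaf", "at0022", dv_text("v"), links = list(l1))))))
  comp <- tiny_composition(tiny_institutional_entry(list(deep)))
  brute <- local({
    n <- 0L
    scan <- function(x) {
      if (is.list(x)) {
        if (inherits(x, "tiss_link")) n <<- n + 1L
        for (el in x) scan(el)
      }
    }
    scan(unclass(comp))
    n
  })
  expect_identical(length(collect_links(comp)), brute)
  paths <- vapply(collect_links(comp), `[[`, character(1), "path")
  expect_match(paths, "at0022\\]$")
})
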
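# Random constraint-tree generator for the ADL parse/print identity
# property. Trees use the registered rm types and the dialect's constructs
# (occurrences, cardinality, any-constraints, slots, labels).
random_label <- function() {
  words <- c("type", "date", "cost", "status", "procedure", "quantity",
             "reason", "comments", "indication", "service")
  paste(sample(words, sample(1:3, 1)), collapse = " ")
}

random_archetype_def <- function(seed) {
  set.seed(seed)
  counter <- new.env(parent = emptyenv())
  counter$n <- 1L
  next_id <- function() {
    counter$n <- counter$n + 1L
    sprintf("at%04d", counter$n)
  }
  rand_interval <- function() {
    lo <- sample(0:1, 1)
    up <- sample(c(lo + sample(0:2, 1), Inf), 1)
    tissehr::adl_interval(lo, up)
  }
  rand_element <- function() {
    tissehr:::c_object("ELEMENT", next_id(), rand_interval(), random_label(),
      attributes = list(tissehr:::c_attribute("value", children = list(
        tissehr:::c_primitive(sample(c("DV_TEXT", "DV_DATE_TIME", "DV_COUNT",
                                       "DV_MONEY"), 1))
      ))))
  }
  rand_slot <- function() {
    tissehr:::c_slot("CLUSTER", next_id(), tissehr::adl_interval(0, Inf),
                     includes = sample(c("openEHR-EHR-CLUSTER.admission.v1",
                                         "openEHR-EHR-CLUSTER.total_costs.v1",
                                         "openEHR-EHR-CLUSTER.costs.v1"),
                                       sample(1:2, 1)),
                     label = random_label())
  }
  rand_cluster <- function(depth) {
    kids <- lapply(seq_len(sample(1:3, 1)), function(i) {
      if (depth > 1 && stats::runif(1) < 0.3) rand_cluster(depth - 1) else rand_element()
    })
    if (stats::runif(1) < 0.2) kids <- c(kids, list(rand_slot()))
    tissehr:::c_object("CLUSTER", next_id(), rand_interval(), random_label(),
      attributes = list(tissehr:::c_attribute(
        "items", tissehr::adl_interval(0, Inf, ordered = sample(c(TRUE, FALSE), 1)),
        kids)))
  }
  kids <- lapply(seq_len(sample(2:5, 1)), function(i) {
    if (stats::runif(1) < 0.3) rand_cluster(2) else rand_element()
  })
  if (stats::runif(1) < 0.5) kids <- c(kids, list(rand_slot()))
  root <- tissehr:::c_object(
    "ADMIN_ENTRY", "at0000", tissehr::adl_interval(1, 1), random_label(),
    attributes = list(tissehr:::c_attribute("data", children = list(
      tissehr:::c_object("ITEM_TREE", next_id(), tissehr::adl_interval(1, 1),
                         "components",
                         attributes = list(tissehr:::c_attribute(
                           "items", tissehr::adl_interval(0, Inf, ordered = FALSE),
                           kids)))
    ))))
  archetype_definition(
    sprintf("openEHR-EHR-ADMIN_ENTRY.random_concept_%d.v1", seed %% 97 + 1), root)
}

expect_def_identical <- function(a, b) {
  expect_identical(format(a$id), format(b$id))
  expect_identical(a$root, b$root)
  expect_identical(a$term_definitions, b$term_definitions)
}
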
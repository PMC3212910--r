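#' Archetype identifiers
#'
#' Archetype identifiers render as `openEHR-EHR-<RM_ENTITY>.<concept>.v<N>`.
#' `parse_archetype_id()` also accepts the short form without the `EHR`
#' segment (`openEHR-CLUSTER.admission.v1`, as used in some archetype
#' inventories) and normalizes it, setting the `normalized` attribute.
#'
#' @param rm_entity the constrained reference-model class, e.g. `ADMIN_ENTRY`.
#' @param concept the domain concept name.
#' @param version positive integer version.
#' @param originator identifier namespace, fixed to `openEHR` here.
#' @param s an identifier string to parse.
#' @return an `archetype_id` object; `format()` gives the canonical string.
#' @examples
#' format(parse_archetype_id("openEHR-CLUSTER.admission.v1"))
#' @export
archetype_id <- function(rm_entity, concept, version = 1L, originator = "openEHR") {
  assert_string(rm_entity, "rm_entity")
  assert_string(concept, "concept")
  if (!is.numeric(version) || length(version) != 1L || version < 1 ||
      version != trunc(version)) {
    stop_tiss("version must be a positive integer", "tiss_value_error")
  }
  structure(list(originator = originator, rm_entity = rm_entity,
                 concept = concept, version = as.integer(version)),
            class = "tiss_archetype_id")
}

#' @rdname archetype_id
#' @export
parse_archetype_id <- function(s) {
  assert_string(s, "archetype id")
  m <- regexec("^openEHR-(EHR-)?([A-Z][A-Z_]*)\\.([a-z][a-z0-9_]*)\\.v([0-9]+)$", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  if (length(parts) == 0L) {
    stop_tiss(sprintf("malformed archetype id: '%s'", s), "tiss_parse_error")
  }
  out <- archetype_id(parts[3], parts[4], as.integer(parts[5]))
  attr(out, "normalized") <- !nzchar(parts[2])
  out
}

#' @export
format.tiss_archetype_id <- function(x, ...) {
  sprintf("%s-EHR-%s.%s.v%d", x$originator, x$rm_entity, x$concept, x$version)
}

#' @export
print.tiss_archetype_id <- function(x, ...) {
  cat("<archetype id>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.tiss_archetype_id <- function(x, ...) format(x)

# Normalize an archetype id string to its canonical long form.
normalize_archetype_id <- function(s) format(parse_archetype_id(s))

#' Occurrence and cardinality intervals
#'
#' Integer intervals written `{l..u}` with `*` for an unbounded upper limit;
#' cardinality intervals additionally carry an ordered/unordered flag.
#'
#' @param lower non-negative integer lower bound.
#' @param upper integer upper bound or `Inf`.
#' @param ordered logical flag (`NA` for plain occurrence intervals).
#' @return an `interval` object.
#' @export
adl_interval <- function(lower, upper, ordered = NA) {
  if (!is.numeric(lower) || lower < 0 || lower != trunc(lower)) {
    stop_tiss("interval lower bound must be a non-negative integer", "tiss_value_error")
  }
  if (!(is.infinite(upper) || (is.numeric(upper) && upper >= 0 && upper == trunc(upper)))) {
    stop_tiss("interval upper bound must be an integer or unbounded", "tiss_value_error")
  }
  if (is.finite(upper) && lower > upper) {
    stop_tiss("interval lower bound exceeds its upper bound", "tiss_value_error")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 ordered = ordered), class = "tiss_interval")
}

#' @export
format.tiss_interval <- function(x, ...) {
  up <- if (is.finite(x$upper)) num_to_str(x$upper) else "*"
  base <- paste0(num_to_str(x$lower), "..", up)
  if (!is.na(x$ordered)) {
    base <- paste0(base, "; ", if (x$ordered) "ordered" else "unordered")
  }
  base
}

interval_contains <- function(outer, inner) {
  inner$lower >= outer$lower && inner$upper <= outer$upper
}

# Constraint-tree node constructors -----------------------------------------

c_object <- function(rm_type, node_id, occurrences = adl_interval(1, 1),
                     label = NULL, attributes = list(), any = FALSE,
                     filler_id = NULL, slot_origin = NULL, binding = NULL,
                     excluded = FALSE) {
  structure(list(kind = "object", rm_type = rm_type, node_id = assert_node_id(node_id),
                 occurrences = occurrences, label = label, attributes = attributes,
                 any = any, filler_id = filler_id, slot_origin = slot_origin,
                 binding = binding, excluded = excluded),
            class = c("tiss_c_object", "tiss_constraint"))
}

c_attribute <- function(name, cardinality = NULL, children = list()) {
  structure(list(kind = "attribute", name = name, cardinality = cardinality,
                 children = children),
            class = c("tiss_c_attribute", "tiss_constraint"))
}

c_primitive <- function(rm_type, pattern = "*") {
  structure(list(kind = "primitive", rm_type = rm_type, pattern = pattern),
            class = c("tiss_c_primitive", "tiss_constraint"))
}

c_slot <- function(rm_type, node_id, occurrences = adl_interval(0, Inf),
                   includes = character(), label = NULL) {
  structure(list(kind = "slot", rm_type = rm_type, node_id = assert_node_id(node_id),
                 occurrences = occurrences, includes = includes, label = label),
            class = c("tiss_c_slot", "tiss_constraint"))
}

#' Archetype definitions
#'
#' Container for a parsed archetype: its identifier, the root constraint
#' tree, and the node-id term definitions. When no term definitions are
#' given they are derived from the constraint labels (the trailing `--`
#' comments of the definition section), with the description defaulting to
#' the term text.
#'
#' @param id an [archetype_id()] (or id string), or `NULL` for an anonymous
#'   definition section.
#' @param root the root constraint node (an object constraint at `at0000`).
#' @param term_definitions named list `node_id -> list(text, description)`.
#' @return an `archetype_definition` object.
#' @export
archetype_definition <- function(id, root, term_definitions = NULL) {
  if (!is.null(id)) {
    if (is.character(id)) id <- parse_archetype_id(id)
    if (!inherits(id, "tiss_archetype_id")) {
      stop_tiss("id must be an archetype id or NULL", "tiss_type_error")
    }
  }
  if (!inherits(root, "tiss_c_object") || !identical(root$node_id, "at0000")) {
    stop_tiss("root must be an object constraint at at0000", "tiss_value_error")
  }
  if (is.null(term_definitions)) {
    term_definitions <- list()
    walk <- function(n) {
      if (n$kind %in% c("object", "slot")) {
        if (!is.null(n$label)) {
          term_definitions[[n$node_id]] <<- list(text = n$label, description = n$label)
        }
        if (n$kind == "object") for (a in n$attributes) for (ch in a$children) walk(ch)
      }
    }
    walk(root)
  }
  structure(list(id = id, root = root, term_definitions = term_definitions),
            class = "tiss_archetype_definition")
}

#' @export
print.tiss_archetype_definition <- function(x, ...) {
  cat("<archetype>", if (!is.null(x$id)) format(x$id) else "(anonymous)", "\n")
  cat("  root:", x$root$rm_type, sprintf("[%s]", x$root$node_id),
      x$root$label %||% "", "\n")
  cat("  terms:", length(x$term_definitions), "\n")
  invisible(x)
}

# Count ELEMENT object constraints in a definition tree.
count_elements <- function(def) {
  n <- 0L
  walk <- function(node) {
    if (node$kind == "object") {
      if (identical(node$rm_type, "ELEMENT")) n <<- n + 1L
      for (a in node$attributes) for (ch in a$children) walk(ch)
    }
  }
  walk(if (inherits(def, "tiss_archetype_definition")) def$root else def)
  n
}

constraint_node_ids <- function(root) {
  ids <- character()
  walk <- function(n) {
    if (n$kind %in% c("object", "slot")) {
      ids <<- c(ids, n$node_id)
      if (n$kind == "object") for (a in n$attributes) for (ch in a$children) walk(ch)
    }
  }
  walk(root)
  ids
}
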
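#' Reference-model type registry
#'
#' The kernel implements the minimal class subset needed to represent every
#' TISS archetype instance: compositions, sections, the clinical and
#' administrative entry families, item structures and elements, plus the
#' extended-model submission hierarchy (SUBMISSION, CLAIM, PROFESSIONAL_CLAIM,
#' INSTITUTIONAL_CLAIM, AUTHORIZATION, ANNEX). `rm_type_parents()` exposes the
#' is-a relation; `is_rm_subtype()` answers substitutability questions, e.g.
#' an INSTITUTIONAL_CLAIM instance satisfies an ADMIN_ENTRY constraint.
#'
#' @return `rm_type_parents()`: a named character vector mapping each type to
#'   its parent; `rm_known_types()`: all registered structural type names;
#'   `is_rm_subtype()`: a logical scalar.
#' @examples
#' is_rm_subtype("INSTITUTIONAL_CLAIM", "ADMIN_ENTRY")
#' @export
rm_type_parents <- function() {
  c(
    ELEMENT = "ITEM", CLUSTER = "ITEM", ITEM = "LOCATABLE",
    ITEM_TREE = "ITEM_STRUCTURE", ITEM_LIST = "ITEM_STRUCTURE",
    ITEM_TABLE = "ITEM_STRUCTURE", ITEM_SINGLE = "ITEM_STRUCTURE",
    ITEM_STRUCTURE = "LOCATABLE",
    SECTION = "CONTENT_ITEM", ENTRY = "CONTENT_ITEM", CONTENT_ITEM = "LOCATABLE",
    CARE_ENTRY = "ENTRY", ADMIN_ENTRY = "ENTRY",
    OBSERVATION = "CARE_ENTRY", EVALUATION = "CARE_ENTRY",
    INSTRUCTION = "CARE_ENTRY", ACTION = "CARE_ENTRY",
    SUBMISSION = "ADMIN_ENTRY", CLAIM = "SUBMISSION",
    PROFESSIONAL_CLAIM = "CLAIM", INSTITUTIONAL_CLAIM = "CLAIM",
    AUTHORIZATION = "SUBMISSION", ANNEX = "SUBMISSION",
    COMPOSITION = "LOCATABLE"
  )
}

#' @rdname rm_type_parents
#' @export
rm_known_types <- function() {
  p <- rm_type_parents()
  unique(c(names(p), unname(p)))
}

#' @rdname rm_type_parents
#' @param type,ancestor reference-model type names.
#' @export
is_rm_subtype <- function(type, ancestor) {
  p <- rm_type_parents()
  t <- type
  while (!is.na(t)) {
    if (identical(t, ancestor)) return(TRUE)
    t <- if (t %in% names(p)) unname(p[[t]]) else NA_character_
  }
  FALSE
}

rm_ancestry <- function(type) {
  p <- rm_type_parents()
  out <- character()
  t <- type
  while (!is.na(t)) {
    out <- c(out, t)
    t <- if (t %in% names(p)) unname(p[[t]]) else NA_character_
  }
  out
}

dv_known_types <- function() {
  c("DV_TEXT", "DV_CODED_TEXT", "DV_DATE_TIME", "DV_DATE", "DV_COUNT",
    "DV_QUANTITY", "DV_MONEY", "DV_IDENTIFIER")
}

#' Archetype node identifiers
#'
#' Node identifiers are `at` followed by at least four digits; `at0000` is
#' reserved for archetype roots, so any node carrying it must also carry an
#' archetype identifier.
#'
#' @param x a character scalar.
#' @return logical scalar.
#' @export
is_node_id <- function(x) {
  is_string(x) && grepl("^at[0-9]{4,}$", x)
}

assert_node_id <- function(x) {
  if (!is_node_id(x)) {
    stop_tiss(sprintf("malformed node id: '%s'", paste(x, collapse = "")), "tiss_value_error")
  }
  x
}
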
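#' @keywords internal
new_locatable <- function(rm_type, name, node_id, archetype_id = NULL,
                          links = list(), fields = list()) {
  assert_string(name, "name")
  assert_node_id(node_id)
  if (!is.null(archetype_id)) assert_string(archetype_id, "archetype_id")
  if (identical(node_id, "at0000") && is.null(archetype_id)) {
    stop_tiss("at0000 is reserved for archetype roots (archetype_id required)",
              "tiss_value_error")
  }
  if (!is.list(links) || !all(vapply(links, inherits, logical(1), "tiss_link"))) {
    stop_tiss("links must be a list of links", "tiss_type_error")
  }
  cls <- paste0("tiss_", tolower(rm_ancestry(rm_type)))
  structure(
    c(list(rm_type = rm_type, name = name, node_id = node_id,
           archetype_id = archetype_id, links = links), fields),
    class = cls
  )
}

is_locatable <- function(x) inherits(x, "tiss_locatable")

#' Reference-model node constructors
#'
#' Constructors for the record structures every claim document is built from:
#' `element()` holds one data value (or `NULL` for explicitly unknown);
#' `cluster()` groups items; `item_tree()`, `item_list()`, `item_table()` and
#' `item_single()` are the item-structure variants an entry's data may take;
#' `section()` groups entries; `composition()` is the document root. Item
#' tables require every row to carry the same element names in the same order.
#'
#' @param name human-readable node name (the archetype term text).
#' @param node_id archetype node id (`atNNNN`); `at0000` only at archetype
#'   roots, together with `archetype_id`.
#' @param value a data value or `NULL`.
#' @param items,rows,item child nodes.
#' @param archetype_id archetype identifier, set on archetype roots only.
#' @param links list of [link_to()] objects.
#' @return a locatable node.
#' @export
element <- function(name, node_id, value = NULL, links = list(), archetype_id = NULL) {
  if (!is.null(value) && !is_dv(value)) {
    stop_tiss("element value must be a data value or NULL", "tiss_type_error")
  }
  new_locatable("ELEMENT", name, node_id, archetype_id, links, list(value = value))
}

#' @rdname element
#' @export
cluster <- function(name, node_id, items, links = list(), archetype_id = NULL) {
  if (!is.list(items) || length(items) < 1L ||
      !all(vapply(items, function(i) inherits(i, "tiss_item"), logical(1)))) {
    stop_tiss("cluster items must be a non-empty list of elements/clusters", "tiss_type_error")
  }
  new_locatable("CLUSTER", name, node_id, archetype_id, links, list(items = items))
}

#' @rdname element
#' @export
item_tree <- function(name, node_id, items = list(), links = list(), archetype_id = NULL) {
  if (!all(vapply(items, function(i) inherits(i, "tiss_item"), logical(1)))) {
    stop_tiss("item tree items must be elements or clusters", "tiss_type_error")
  }
  new_locatable("ITEM_TREE", name, node_id, archetype_id, links, list(items = items))
}

#' @rdname element
#' @export
item_list <- function(name, node_id, items = list(), links = list(), archetype_id = NULL) {
  if (!all(vapply(items, function(i) inherits(i, "tiss_element"), logical(1)))) {
    stop_tiss("item list items must be elements", "tiss_type_error")
  }
  new_locatable("ITEM_LIST", name, node_id, archetype_id, links, list(items = items))
}

#' @rdname element
#' @export
item_table <- function(name, node_id, rows = list(), links = list(), archetype_id = NULL) {
  if (!all(vapply(rows, function(r) inherits(r, "tiss_cluster"), logical(1)))) {
    stop_tiss("item table rows must be clusters", "tiss_type_error")
  }
  if (length(rows) > 1L) {
    sig <- function(r) paste(vapply(r$items, `[[`, character(1), "name"), collapse = "\r")
    sigs <- vapply(rows, sig, character(1))
    if (length(unique(sigs)) != 1L) {
      stop_tiss("item table rows must contain the same element names in the same order",
                "tiss_value_error")
    }
  }
  new_locatable("ITEM_TABLE", name, node_id, archetype_id, links, list(rows = rows))
}

#' @rdname element
#' @export
item_single <- function(name, node_id, item, links = list(), archetype_id = NULL) {
  if (!inherits(item, "tiss_element")) {
    stop_tiss("item single holds one element", "tiss_type_error")
  }
  new_locatable("ITEM_SINGLE", name, node_id, archetype_id, links, list(item = item))
}

make_entry <- function(rm_type, name, node_id, archetype_id, subject, data,
                       provider = NULL, other_participations = list(),
                       links = list(), extra = list()) {
  if (!is_party(subject)) stop_tiss("subject must be a party", "tiss_type_error")
  if (!is.null(provider) && !is_party(provider)) {
    stop_tiss("provider must be a party or NULL", "tiss_type_error")
  }
  if (!all(vapply(other_participations, inherits, logical(1), "tiss_participation"))) {
    stop_tiss("other_participations must be participations", "tiss_type_error")
  }
  if (!inherits(data, "tiss_item_structure")) {
    stop_tiss("entry data must be an item structure", "tiss_type_error")
  }
  new_locatable(rm_type, name, node_id, archetype_id, links,
                c(list(subject = subject, provider = provider,
                       other_participations = other_participations, data = data),
                  extra))
}

#' Entry constructors
#'
#' Entries carry the record content of a composition. Clinical content lives
#' in the CARE_ENTRY family — `observation()`, `evaluation()` (e.g. a patient
#' evaluation with diagnoses), `instruction()` and `action()` (e.g. performed
#' claim services) — while administrative content such as claim headers lives
#' in `admin_entry()`. Every entry names its subject (the patient), optionally
#' the provider who recorded it, and further participants such as the payer.
#'
#' @inheritParams element
#' @param subject the record subject, a party proxy.
#' @param data an item structure with the entry's values.
#' @param provider optional recording provider.
#' @param other_participations list of [participation()] objects.
#' @return an entry node.
#' @export
admin_entry <- function(name, node_id = "at0000", archetype_id = NULL, subject, data,
                        provider = NULL, other_participations = list(), links = list()) {
  make_entry("ADMIN_ENTRY", name, node_id, archetype_id, subject, data,
             provider, other_participations, links)
}

#' @rdname admin_entry
#' @export
observation <- function(name, node_id = "at0000", archetype_id = NULL, subject, data,
                        provider = NULL, other_participations = list(), links = list()) {
  make_entry("OBSERVATION", name, node_id, archetype_id, subject, data,
             provider, other_participations, links)
}

#' @rdname admin_entry
#' @export
evaluation <- function(name, node_id = "at0000", archetype_id = NULL, subject, data,
                       provider = NULL, other_participations = list(), links = list()) {
  make_entry("EVALUATION", name, node_id, archetype_id, subject, data,
             provider, other_participations, links)
}

#' @rdname admin_entry
#' @export
instruction <- function(name, node_id = "at0000", archetype_id = NULL, subject, data,
                        provider = NULL, other_participations = list(), links = list()) {
  make_entry("INSTRUCTION", name, node_id, archetype_id, subject, data,
             provider, other_participations, links)
}

#' @rdname admin_entry
#' @export
action <- function(name, node_id = "at0000", archetype_id = NULL, subject, data,
                   provider = NULL, other_participations = list(), links = list()) {
  make_entry("ACTION", name, node_id, archetype_id, subject, data,
             provider, other_participations, links)
}

#' @rdname element
#' @export
section <- function(name, node_id, items = list(), links = list(), archetype_id = NULL) {
  ok <- all(vapply(items, function(i) inherits(i, "tiss_content_item"), logical(1)))
  if (!ok) stop_tiss("section items must be sections or entries", "tiss_type_error")
  new_locatable("SECTION", name, node_id, archetype_id, links, list(items = items))
}

#' Composition documents
#'
#' A composition is the unit of committal and exchange: one claim,
#' authorization request/response, or evaluation document. In extended mode a
#' composition additionally carries an `ism_transition` (the current claim
#' status) and a `lifecycle` history of such transitions; in the plain
#' reference model the status lives in a status element of the admin entry.
#'
#' @inheritParams element
#' @param composer the party who composed the document.
#' @param context_start_time ISO-8601 timestamp of the documented event.
#' @param content list of sections/entries.
#' @param ism_transition optional [ism_transition()] (extended mode).
#' @param lifecycle list of [ism_transition()] records, oldest first.
#' @param template optional name of the form template the document instantiates.
#' @return a composition node.
#' @export
composition <- function(name, node_id = "at0000", archetype_id = NULL, composer,
                        context_start_time, content = list(), ism_transition = NULL,
                        lifecycle = list(), template = NULL, links = list()) {
  if (!is_party(composer)) stop_tiss("composer must be a party", "tiss_type_error")
  if (!all(vapply(content, function(i) inherits(i, "tiss_content_item"), logical(1)))) {
    stop_tiss("composition content must be sections or entries", "tiss_type_error")
  }
  if (!is.null(ism_transition) && !inherits(ism_transition, "tiss_ism_transition")) {
    stop_tiss("ism_transition must be an ism_transition or NULL", "tiss_type_error")
  }
  if (!all(vapply(lifecycle, inherits, logical(1), "tiss_ism_transition"))) {
    stop_tiss("lifecycle must be a list of ism_transitions", "tiss_type_error")
  }
  if (!is.null(template)) assert_string(template, "template")
  new_locatable("COMPOSITION", name, node_id, archetype_id, links,
                list(template = template,
                     context_start_time = canonical_datetime(context_start_time),
                     composer = composer, content = content,
                     ism_transition = ism_transition, lifecycle = lifecycle))
}

# Fields along which instance trees are traversed (paths, link collection).
tiss_child_fields <- function(rm_type) {
  if (is_rm_subtype(rm_type, "ENTRY")) return("data")
  switch(rm_type,
    COMPOSITION = "content",
    SECTION = "items",
    CLUSTER = "items",
    ITEM_TREE = "items",
    ITEM_LIST = "items",
    ITEM_TABLE = "rows",
    ITEM_SINGLE = "item",
    character()
  )
}

child_nodes <- function(node, field) {
  v <- node[[field]]
  if (is.null(v)) return(list())
  if (is_locatable(v)) list(v) else v
}

#' @export
print.tiss_locatable <- function(x, ...) {
  id <- if (!is.null(x$archetype_id)) paste0(" <", x$archetype_id, ">") else ""
  cat(sprintf("%s[%s]%s -- %s\n", x$rm_type, x$node_id, id, x$name))
  if (x$rm_type == "ELEMENT" && !is.null(x$value)) {
    cat("  value:", format(x$value), "\n")
  }
  for (f in tiss_child_fields(x$rm_type)) {
    kids <- child_nodes(x, f)
    if (length(kids)) cat(sprintf("  %s: %d child node(s)\n", f, length(kids)))
  }
  invisible(x)
}
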
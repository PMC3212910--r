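#' Canonical JSON and XML serialization
#'
#' Compositions and extracts serialize to a canonical JSON form and an
#' equivalent canonical XML form (UTF-8). Both derive from the same canonical
#' tree, so a round trip through either format — and across formats — yields
#' a structurally equal object. In the XML form the element name is the
#' reference-model attribute name, the node id is carried in the
#' `archetype_node_id` attribute and the reference-model type in `rm_type`;
#' scalar fields are XML attributes and structured fields child elements.
#' Monetary amounts are rounded half-to-even to two decimals at serialization.
#'
#' @param x a [composition()] or extract.
#' @param pretty pretty-print JSON.
#' @param txt serialized text to read back.
#' @return `to_tiss_json()` / `to_tiss_xml()` return a character scalar;
#'   the readers return the reconstructed object.
#' @export
to_tiss_json <- function(x, pretty = FALSE) {
  as.character(jsonlite::toJSON(as_rm_list(x), auto_unbox = TRUE, digits = NA,
                                pretty = pretty, null = "null"))
}

#' @rdname to_tiss_json
#' @export
from_tiss_json <- function(txt) {
  rm_from_list(jsonlite::fromJSON(txt, simplifyVector = FALSE))
}

# Fields serialized as repeated child elements; everything else structured is
# a single child. Needed so the XML reader can rebuild lists of length one.
xml_list_fields <- function() {
  c("items", "rows", "content", "links", "identifiers", "other_participations",
    "participants", "lifecycle", "compositions")
}

xml_logical_fields <- function() "is_response"

canon_fill_xml <- function(node, l) {
  for (nm in names(l)) {
    v <- l[[nm]]
    if (nm %in% c("_rm", "_dv", "_k")) {
      attr_nm <- switch(nm, "_rm" = "rm_type", "_dv" = "dv_type", "_k" = "kind")
      xml2::xml_set_attr(node, attr_nm, v)
    } else if (is.list(v)) {
      if (!is.null(v$`_rm`) || !is.null(v$`_dv`) || !is.null(v$`_k`)) {
        canon_fill_xml(xml2::xml_add_child(node, nm), v)
      } else {
        for (el in v) canon_fill_xml(xml2::xml_add_child(node, nm), el)
      }
    } else if (is.numeric(v)) {
      xml2::xml_set_attr(node, nm, num_to_str(v))
    } else if (is.logical(v)) {
      xml2::xml_set_attr(node, nm, if (v) "true" else "false")
    } else {
      xml2::xml_set_attr(node, nm, as.character(v))
    }
  }
  node
}

#' @rdname to_tiss_json
#' @export
to_tiss_xml <- function(x) {
  l <- as_rm_list(x)
  tag <- tolower(l$`_rm` %||% l$`_k`)
  doc <- xml2::xml_new_root(tag)
  canon_fill_xml(doc, l)
  as.character(doc)
}

xml_to_canon <- function(node) {
  l <- list()
  attrs <- xml2::xml_attrs(node)
  dvk <- unname(attrs["dv_type"])
  for (nm in names(attrs)) {
    v <- unname(attrs[[nm]])
    key <- switch(nm, rm_type = "_rm", dv_type = "_dv", kind = "_k", nm)
    if (key %in% c("_rm", "_dv", "_k")) {
      l[[key]] <- v
    } else if (nm %in% xml_logical_fields()) {
      l[[nm]] <- identical(v, "true")
    } else if (nm %in% c("magnitude", "amount") ||
               (identical(nm, "value") && !is.na(dvk) && identical(dvk, "DV_COUNT"))) {
      l[[nm]] <- as.numeric(v)
    } else {
      l[[nm]] <- v
    }
  }
  for (child in xml2::xml_children(node)) {
    tag <- xml2::xml_name(child)
    cv <- xml_to_canon(child)
    if (tag %in% xml_list_fields()) {
      l[[tag]] <- c(l[[tag]] %||% list(), list(cv))
    } else {
      l[[tag]] <- cv
    }
  }
  l
}

#' @rdname to_tiss_json
#' @export
from_tiss_xml <- function(txt) {
  doc <- xml2::read_xml(txt)
  rm_from_list(xml_to_canon(doc))
}
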
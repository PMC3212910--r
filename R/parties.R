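#' Party references, participations and links
#'
#' Demographic entities exchanged between systems must be resolvable in the
#' target system, so they are represented as `party_identified()` carrying at
#' least one identifier (provider registry number, health-plan number, patient
#' number). `party_self()` denotes the record subject without identification.
#' `participation()` attaches further actors to an entry (the payer, the
#' billing manager, institutional staff) with a functional role, and
#' `link_to()` expresses relationships between record nodes, e.g. a performed
#' service linked to the diagnoses that justify it.
#'
#' @param name display name of the party.
#' @param identifiers list of [dv_identifier()] values.
#' @param performer a party proxy.
#' @param func the participation function, e.g. `"payer"`.
#' @param mode optional participation mode.
#' @param meaning,type,target link fields; `target` is a reference string
#'   (composition id plus path).
#' @return party / participation / link objects.
#' @export
party_identified <- function(name, identifiers = list()) {
  assert_string(name, "name")
  if (!is.list(identifiers) || !all(vapply(identifiers, function(i) {
    is_dv(i) && dv_kind(i) == "DV_IDENTIFIER"
  }, logical(1)))) {
    stop_tiss("identifiers must be a list of dv_identifier values", "tiss_type_error")
  }
  structure(list(party_type = "PARTY_IDENTIFIED", name = name, identifiers = identifiers),
            class = c("tiss_party_identified", "tiss_party"))
}

#' @rdname party_identified
#' @export
party_self <- function() {
  structure(list(party_type = "PARTY_SELF"), class = c("tiss_party_self", "tiss_party"))
}

is_party <- function(x) inherits(x, "tiss_party")

#' @rdname party_identified
#' @export
participation <- function(performer, func, mode = NULL) {
  if (!is_party(performer)) stop_tiss("performer must be a party", "tiss_type_error")
  assert_string(func, "function")
  out <- list(performer = performer)
  out[["function"]] <- func
  out$mode <- if (is.null(mode)) NULL else assert_string(mode, "mode")
  structure(out, class = "tiss_participation")
}

#' @rdname party_identified
#' @export
link_to <- function(meaning, type, target) {
  structure(list(
    meaning = assert_string(meaning, "meaning"),
    type = assert_string(type, "type"),
    target = assert_string(target, "target")
  ), class = "tiss_link")
}

#' @export
print.tiss_party <- function(x, ...) {
  if (x$party_type == "PARTY_SELF") {
    cat("<PARTY_SELF>\n")
  } else {
    ids <- vapply(x$identifiers, format, character(1))
    cat(sprintf("<PARTY_IDENTIFIED> %s [%s]\n", x$name, paste(ids, collapse = ", ")))
  }
  invisible(x)
}
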